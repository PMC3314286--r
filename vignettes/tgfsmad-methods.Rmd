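---
title: "Modeling TIF1gamma regulation of TGF-beta/Smad signaling"
author: "tgfsmad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling TIF1gamma regulation of TGF-beta/Smad signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgfsmad)
```

## The biological question

TIF1gamma (TRIM33) has been reported both as a repressor of TGF-beta/Smad
signaling — it mono-ubiquitinates Smad4 within nuclear phospho-Smad2/Smad4
complexes, driving Smad4 export — and as an alternative positive partner that
binds receptor-phosphorylated Smad2 independently of Smad4. `tgfsmad`
implements three mass-action ODE mechanisms on a shared signaling core so the
two seemingly contradictory observations can be compared dynamically:

* **REPRESSOR** — TIF1gamma acts purely catalytically on nuclear
  phospho-Smad2/Smad4 complexes (`pS24n`), converting them into nuclear
  ubiquitinated Smad4 (`Smad4ub`) plus free nuclear phospho-Smad2. The
  transient TIF1gamma-Smad complex is elided, exactly as the nuclear
  phosphatase (PPase) is treated: the interaction is assumed fast, so only
  the catalytic conversion survives.
* **COMPETITION** — TIF1gamma reversibly sequesters nuclear phospho-Smad2
  and nuclear Smad4, competing with heteromeric complex formation. No
  ubiquitination occurs.
* **INTEGRATED** — TIF1gamma binds `pS24n` into a transient ternary complex
  (`pS24nTIF1g`). The ternary complex either dissociates back or resolves by
  Smad4 mono-ubiquitination into `Smad4ub` plus a phospho-Smad2-TIF1gamma
  complex (`pS2nTIF1g`); `pS2nTIF1g` is produced *only* by this route, never
  by direct association. Exported `Smad4ub` is recycled in the cytoplasm by
  the FAM/USP9x deubiquitinase.

The transcriptional readout throughout is `pS24n`, the pool of nuclear
phospho-Smad2/Smad4 heterodimers *not* bound to TIF1gamma: these are the
transcription-competent complexes. The TIF1gamma-bound ternary pool is
deliberately excluded from the readout.

## The signaling core

The core merges two published module families through the endosomal
ligand-receptor complex `LRe`:

1. **Receptor trafficking.** Type I and II receptors are synthesized,
   degraded constitutively, internalized, and recycled. Ligand joins both
   receptor types into a surface signaling complex that undergoes
   ligand-induced degradation or internalization to `LRe`; recycling of
   `LRe` returns receptors but degrades the ligand molecule. Receptor
   abundances in this literature are molecule counts per cell; they are
   converted to nM through the 2.27e-12 L cell volume
   (`molecules_to_concentration()`), so the merged system is uniformly in
   nM and seconds.
2. **Smad nucleocytoplasmic shuttling.** `LRe` phosphorylates cytoplasmic
   Smad2; phospho-Smad2 forms heteromeric complexes with Smad4 and homomeric
   complexes with itself in both compartments; monomers shuttle in and out
   of the nucleus while complexes are imported 5.7-fold faster (the complex
   import factor, CIF) and are not exported; a nuclear phosphatase
   (1 nM) dephosphorylates only monomeric phospho-Smad2, so complexes must
   dissociate before the signal can be erased.

Total Smad2 (60.6 nM) and Smad4 (50 nM) are conserved along every
trajectory, as are TIF1gamma, FAM, and PPase; conservation is asserted
symbolically at build time (each moiety's weight vector annihilates the
stoichiometric matrix) and numerically along trajectories
(`conservation_drift()` stays below 1e-6 relative).

## Parameters, units, and defaults

Everything is nM and seconds. Trafficking constants follow the published
trafficking model: internalization 1/3 min^-1, recycling 1/33 min^-1,
constitutive degradation 1/36 min^-1, ligand-induced degradation
1/4 min^-1, synthesis 8 molecules min^-1 converted to nM/s. Shuttling
constants follow the published shuttling model: complex association
k_on = 1.8e-3 nM^-1 s^-1 and dissociation k_off = 1.6e-2 s^-1, PPase
dephosphorylation 6.57e-3 nM^-1 s^-1, monomer import/export on the
2.6e-3-5.6e-3 s^-1 scale, CIF = 5.7.

Three conventions tie the TIF1gamma arm to the core:

* ternary-complex formation/dissociation constants equal the
  phospho-Smad2/Smad4 constants (`k_on_pS24nTIF1g = k_on`,
  `k_off_pS24nTIF1g = k_off_pS2nTIF1g = k_off`);
* ubiquitination/deubiquitination kinetics mirror
  phosphorylation/dephosphorylation (`k_ub = 6.57e-3 s^-1` at the 1 nM
  enzyme scale, `k_dub = k_dephos`);
* nuclear export of ubiquitinated Smad4 is twice the Smad4 nuclear import
  constant (`k_in_S4ub = 2 * k_in_S4`), reflecting the weaker nuclear
  retention of Smad4ub.

Two merge-level constants have no published value in the units of the
merged system and were calibrated once, as part of model construction:

* `k_a` (ligand + RI + RII association, 0.15 nM^-2 s^-1) was set so that
  receptor occupancy saturates for ligand doses of about 1 nM and above
  while 0.1 nM remains clearly sub-saturating — the dose behavior the
  source trafficking model exhibits;
* `k_phos` (Smad2 phosphorylation per nM of `LRe`, 4e-3 nM^-1 s^-1) was
  set so that a saturating dose phosphorylates the Smad2 pool on the
  tens-of-minutes timescale of the shuttling model, giving a nuclear
  complex peak near one hour.

Neither constant is revisited by any analysis; both are ordinary entries of
`default_parameters()` and can be overridden.

Compartment volumes: cytoplasm 2.27e-12 L (also the reference volume for
receptor pools and for reporting conserved totals), nucleus 1.0e-12 L,
extracellular medium 1e-11 L per cell. The extracellular volume only
matters with ligand depletion enabled, where it sets how much ligand a cell
can drain; 10 cell volumes of medium per cell makes depletion visible at
nanomolar doses without dominating the response.

## Simulation engine

Before any stimulation the ligand-free system is integrated to steady state
(residual below 1e-10 nM/s) and that state is the t = 0 condition — the
basal condition of an unstimulated cell, with zero basal `pS24n`.
Integration uses a stiff-capable adaptive solver (`lsoda`, rtol 1e-8, atol
1e-12 nM) because binding (~seconds) and trafficking/recycling (~hours)
timescales differ by orders of magnitude. The integration restarts at every
protocol discontinuity (stimulus onsets and offsets, pulse edges), and
those times are inserted into the output grid, so input edges are never
smeared by the step controller. Concentrations marginally below zero from
integrator undershoot are clamped at 0; undershoot beyond -1e-9 nM warns
and beyond -1e-6 nM aborts, since that signals a solver rather than a model
problem.

Ligand depletion is a build-time variant flag: the extracellular ligand
becomes a state variable consumed stoichiometrically (with volume
conversion) by surface-complex formation and not returned on recycling; the
protocol then only places boluses. This is a modeling choice — the cited
depletion mechanism is not published as equations — and it is switchable.

## Computational experiments and their defaults

The scan grids are configuration, not constants: TIF1gamma 0-50 nM (50 nM
equals the total Smad4 pool, so the ratio axis spans 0-1 and beyond),
one-at-a-time multipliers {1/4, 1/2, 1, 2, 4}, durations logarithmic from
5 min to 48 h. The kinetic sensitivity scans probe the INTEGRATED model at
10 nM TIF1gamma — the mid-range dose of the scan — and FAM at 1 nM
(contrasted with 10 nM for the deubiquitination constant). The scalar
sensitivity index is (max - min) peak `pS24n` over the multiplier grid,
divided by the multiplier-1 peak.

For pulsed stimulation, "similar to sustained" is operationalized as: all
inter-pulse troughs of `pS24n` (after the first period) stay at or above
50% of the sustained response at the same times. The threshold is
configurable; no published number exists. The default pulse width is 5 min.

Response surfaces fix Smad4 at 50 nM, vary TIF1gamma through the
TIF1gamma/Smad4 ratio, and normalize each surface to its own global
maximum (100%). Peaks are read from the output grid (2-minute resolution by
default); grid refinement moves peak values by well under one percent.

## Fitting transcriptional data

The model's testable transcriptional prediction is the *relative* `pS24n`
curve over TIF1gamma/Smad4 ratios: peak `pS24n` per ratio normalized to the
ratio-0 peak (`predict_relative_signal()`). Measured fold changes are
mapped onto it by an affine least-squares fit
`fold_change ~ a * curve(ratio) + b` — affine rather than pure scaling
because fold-change data have a floor of 1 for unresponsive genes; pure
scaling is available as an option, as are inverse-variance weights and an
AUC-based statistic instead of the peak. Peak response is the default
fitted quantity because the transcriptional proxy throughout the analysis
is the magnitude of `pS24n`; genes are fitted separately. Between grid
points the curve is interpolated piecewise-linearly, which is
shape-preserving for this monotone curve and cannot overshoot. Kinetic
constants are never refitted — only the two transcription-scaling numbers.

## What the synthetic data emulate — and what they do not

`generate_ratio_dataset()` emulates qPCR fold-change measurements at known
TIF1gamma/Smad4 ratios: replicate draws centered on an affine transform of
the model curve under multiplicative lognormal noise (fold changes are
ratio-scale and strictly positive; additive Gaussian noise is available).
`generate_knockdown_timecourse()` emulates the siRNA experiment that
produces those ratios: the silenced protein drops to a nadir and recovers
single-exponentially toward its basal level as siRNA is diluted — the
functional form is this package's choice, since densitometry traces carry
no stated form. All randomness flows from a single integer seed and
generation is bit-reproducible.

What passing the recovery tests shows is that the fitting stage is unbiased
and consistent *under the assumed noise model*. Real qPCR data add
normalization error against the reference gene, day-to-day transfection
variability, and ratio measurement error from densitometry, none of which
are simulated; the synthetic data validate the pipeline's statistics, not
the wet-lab error structure.

## Numerical choices and degenerate inputs

* Peaks use the first attaining time on ties.
* A zero baseline (ratio-0 peak of zero) makes the relative curve
  undefined and is reported as an error rather than normalized.
* An all-zero response surface is reported, not normalized.
* Fits require at least 3 distinct ratios; a constant predicted curve is a
  rank-deficient design and is refused.
* SBML export targets Level 3 Version 1 with explicit nanomole/liter and
  second units; import accepts the same mass-action rate-law family
  (one compartment size times one rate constant times species
  concentrations) and rejects anything else with the offending reaction id.
  The clamped ligand input of non-depleting models is encoded as a
  boundary-condition species used as a modifier. Validation is this
  package's structural consistency checker.

## Problem sizes

The shipped analyses use 6-12 h horizons at 2-3 min output resolution,
9-point TIF1gamma grids, 5-point multiplier grids and 200-replicate
synthetic recovery studies; these sizes make every figure-level analysis
reproducible in seconds on a single core while leaving peak estimates
grid-converged to well under a percent.

## Known limitations

* Smad3 is not a distinct species; the R-Smad pool is Smad2 only.
* No transcription/translation of target genes inside the ODE system — the
  affine transcription scaling is the only link to mRNA levels.
* No receptor-level TIF1gamma effects, no stochastic simulation, no delays,
  no spatial structure.
* The depletion mechanism and the extracellular volume per cell are
  modeling choices; depletion conclusions should be read as qualitative.
* The COMPETITION variant implements pure reversible sequestration (no
  ubiquitination), the strictest reading of the alternative-pathway
  hypothesis.

## A worked example

```{r example, eval = FALSE}
sc <- scan_tif1g("INTEGRATED", tif1g_grid = c(0, 10, 25, 50))
sc$summary

curve <- predict_relative_signal(c(0, 0.25, 0.5, 1, 2))
cfg <- synth_config(ratios = curve$ratio, a = 3, b = 1, sd = 0.1, n = 3,
                    seed = 1)
fit_scaling(generate_ratio_dataset(cfg, curve), curve)
```
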