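# tgfsmad

Dynamic mass-action modeling of TGF-β/Smad signal transduction under
regulation by the nuclear factor TIF1γ (TRIM33), for systems biologists who
want to test mechanistic hypotheses about TIF1γ against signaling dynamics
rather than endpoint measurements.

## The model

TIF1γ has been described both as a repressor of Smad signaling (it
mono-ubiquitinates Smad4 inside nuclear phospho-Smad2–Smad4 complexes,
driving Smad4 export) and as an alternative positive partner of
phospho-Smad2. The package builds a shared ODE core — receptor trafficking
(synthesis, internalization, recycling, ligand-induced degradation) merged
with Smad nucleocytoplasmic shuttling through the endosomal ligand-receptor
complex LRe — and mounts three TIF1γ mechanisms on it:

* **REPRESSOR**: catalytic conversion
  `TIF1γ + pS24n → TIF1γ + pSmad2_n + Smad4ub_n` (transient complex elided,
  like the nuclear phosphatase step);
* **COMPETITION**: reversible sequestration `TIF1γ + pSmad2_n ⇌ pS2nTIF1γ`
  and `TIF1γ + Smad4_n ⇌ S4nTIF1γ`, no ubiquitination;
* **INTEGRATED**: a transient ternary complex
  `pS24n + TIF1γ ⇌ pS24nTIF1γ → pS2nTIF1γ + Smad4ub_n`, with Smad4ub
  exported (at twice the Smad4 import rate) and recycled in the cytoplasm
  by the FAM/USP9x deubiquitinase.

All species are in nM (receptor counts are converted through the
2.27×10⁻¹² L cell volume), time is in seconds, and the Smad2, Smad4, TIF1γ,
FAM and PPase pools are exactly conserved. The transcriptional readout is
`pS24n`, the nuclear phospho-Smad2–Smad4 pool not bound to TIF1γ. On top of
the integrator sit the figure-level analyses: TIF1γ concentration scans per
variant, one-at-a-time kinetic sensitivity, dose/duration responses,
ratio × duration response surfaces, pulsed-versus-sustained stimulation
(with optional ligand depletion), an affine fit of fold-change data to the
predicted relative `pS24n` curve, a seeded synthetic-data generator, and
SBML L3V1 import/export.

## Worked example

```r
library(tgfsmad)

# graded TIF1γ effect on the peak nuclear Smad complex signal
sc <- scan_tif1g("INTEGRATED", tif1g_grid = c(0, 10, 25, 50))
sc$summary
#>   tif1g peak_pS24n t_peak
#> 1     0  48.122387   3840
#> 2    10  36.687490   3840
#> 3    25  22.228079   3600
#> 4    50   9.666644   3360
```

At a sustained 10 nM TGF-β input the TIF1γ-free model peaks at ~48 nM
`pS24n` about an hour after stimulation; raising TIF1γ toward the 50 nM
Smad4 pool suppresses the peak gradually rather than switching it off —
the behavior that distinguishes the integrated mechanism from the
all-or-nothing repressor and the nearly inert competition variants.

```r
# predicted relative signal over TIF1γ/Smad4 ratios, and a fit of
# (synthetic) fold-change data to it
curve <- predict_relative_signal(c(0, 0.25, 0.5, 1, 2))
curve
#>   ratio    signal   relative
#> 1  0.00 48.122387 1.00000000
#> 2  0.25 33.993038 0.70638719
#> 3  0.50 22.228079 0.46190725
#> 4  1.00  9.666644 0.20087624
#> 5  2.00  4.001971 0.08316235

cfg <- synth_config(ratios = curve$ratio, a = 3, b = 1, sd = 0.1, n = 3, seed = 1)
fit_scaling(generate_ratio_dataset(cfg, curve), curve)
#> Transcription-scaling fit (affine): a = 2.889181, b = 1.084658, RSS = 0.7271762 over 15 points
```

The fitted `a` and `b` map the dimensionless model curve onto fold-change
units; with 10% multiplicative noise and three replicates the planted
scale of 3 is recovered within a few percent.

A command-line wrapper over the same functions ships in `exec/tgfsmad`:

```sh
Rscript exec/tgfsmad scan-tif1g --out results/scan --seed 1
Rscript exec/tgfsmad export-sbml --variant INTEGRATED --out results/sbml
```

Every command writes its result CSV/JSON plus a `manifest.json` with the
config hash, seed and package version.

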