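# Seeded synthetic stand-ins for the wet-lab measurements: qPCR-style
# fold-change datasets whose expectation is an affine transform of the model's
# relative pS24n curve, and knockdown-recovery time courses producing the
# TIF1g/Smad4 ratio series. All randomness flows from a single seed.

#' Configuration for a synthetic fold-change dataset
#'
#' @param ratios TIF1g/Smad4 ratio grid.
#' @param a True transcription scale.
#' @param b True offset (floor of 1 emulates an unresponsive-gene baseline).
#' @param noise `"multiplicative_lognormal"` (default; qPCR fold-changes are
#'   ratio-scale and strictly positive) or `"additive_gaussian"`.
#' @param sd Noise magnitude: sdlog for the lognormal model, absolute sd for
#'   the Gaussian one.
#' @param n Replicates per ratio (>= 1).
#' @param gene Gene label attached to the rows.
#' @param seed Integer seed fixing all randomness.
#' @return A `tgf_synth_config` list.
#' @export
synth_config <- function(ratios = c(0, 0.1, 0.25, 0.5, 1, 1.5, 2),
                         a = 3, b = 1,
                         noise = c("multiplicative_lognormal", "additive_gaussian"),
                         sd = 0.1, n = 3, gene = "CDH2", seed = 1L) {
  noise <- match.arg(noise)
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (n < 1) stop("need at least one replicate", call. = FALSE)
  structure(list(ratios = ratios, a = a, b = b, noise = noise, sd = sd,
                 n = as.integer(n), gene = gene, seed = as.integer(seed)),
            class = "tgf_synth_config")
}

#' Generate a synthetic fold-change-versus-ratio dataset
#'
#' Draws replicate fold changes centered on `a * curve(ratio) + b` under the
#' configured noise model. Re-running with the same configuration is
#' bit-identical.
#'
#' @param cfg A [synth_config()].
#' @param curve Relative-signal curve (data.frame with `ratio`, `relative`),
#'   typically from [predict_relative_signal()].
#' @return A ratio dataset: data.frame with columns `ratio`, `fold_change`,
#'   `sd` (per-ratio sample sd), `gene`, `n` and one row per replicate.
#' @export
generate_ratio_dataset <- function(cfg, curve) {
  stopifnot(inherits(cfg, "tgf_synth_config"))
  mu <- cfg$a * .curve_at(curve, cfg$ratios) + cfg$b
  if (any(mu < 0) && cfg$noise == "multiplicative_lognormal")
    stop("lognormal noise requires nonnegative means", call. = FALSE)
  old <- exists(".Random.seed", envir = globalenv())
  if (old) saved <- get(".Random.seed", envir = globalenv())
  set.seed(cfg$seed)
  on.exit({
    if (old) assign(".Random.seed", saved, envir = globalenv())
  }, add = TRUE)
  out <- do.call(rbind, lapply(seq_along(cfg$ratios), function(i) {
    fc <- switch(cfg$noise,
      multiplicative_lognormal = mu[i] * exp(stats::rnorm(cfg$n, 0, cfg$sd)),
      additive_gaussian = pmax(0, mu[i] + stats::rnorm(cfg$n, 0, cfg$sd)))
    data.frame(ratio = cfg$ratios[i], fold_change = fc,
               sd = if (cfg$n > 1) stats::sd(fc) else 0,
               gene = cfg$gene, n = cfg$n, stringsAsFactors = FALSE)
  }))
  attr(out, "config") <- cfg
  out
}

#' Synthetic siRNA knockdown-recovery time course
#'
#' Emulates a transient knockdown: the targeted protein drops to
#' `nadir_fraction` of its basal level at transfection and recovers
#' single-exponentially as siRNA is diluted and mRNA turns over,
#' `level(t) = 1 - (1 - nadir_fraction) * exp(-recovery_rate * t)`.
#' Emits the TIF1g/Smad4 ratio series used downstream.
#'
#' @param protein Which protein is silenced: `"TIF1g"` or `"Smad4"`.
#' @param nadir_fraction Remaining fraction at day 0 (0 <= x < 1).
#' @param recovery_rate Recovery rate (per day, > 0).
#' @param days Observation days (numeric vector).
#' @param noise_sd Optional multiplicative lognormal observation noise (sdlog).
#' @param seed Integer seed.
#' @return A data.frame with columns `day`, `level` (silenced protein,
#'   fraction of basal), `partner_level`, `ratio` (TIF1g/Smad4).
#' @export
generate_knockdown_timecourse <- function(protein = c("TIF1g", "Smad4"),
                                          nadir_fraction = 0.05,
                                          recovery_rate = 0.5,
                                          days = 0:10, noise_sd = 0,
                                          seed = 1L) {
  protein <- match.arg(protein)
  if (nadir_fraction < 0 || nadir_fraction >= 1)
    stop("nadir_fraction must be in [0, 1)", call. = FALSE)
  if (recovery_rate <= 0) stop("recovery_rate must be > 0", call. = FALSE)
  level <- 1 - (1 - nadir_fraction) * exp(-recovery_rate * days)
  partner <- rep(1, length(days))
  if (noise_sd > 0) {
    old <- exists(".Random.seed", envir = globalenv())
    if (old) saved <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit({
      if (old) assign(".Random.seed", saved, envir = globalenv())
    }, add = TRUE)
    level <- level * exp(stats::rnorm(length(days), 0, noise_sd))
    partner <- partner * exp(stats::rnorm(length(days), 0, noise_sd))
  }
  ratio <- if (protein == "TIF1g") level / partner else partner / level
  data.frame(day = days, protein = protein, level = level,
             partner_level = partner, ratio = ratio,
             stringsAsFactors = FALSE)
}
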