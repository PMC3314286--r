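# Mapping the model's relative pS24n signal onto transcriptional fold-change
# measurements taken at varying TIF1g/Smad4 ratios: the model predicts the
# shape, and only an affine transcription scaling (scale a, offset b) is
# fitted; kinetic constants are never refitted.

#' Predicted relative pS24n signal over TIF1g/Smad4 ratios
#'
#' Simulates the model at each ratio (Smad4 total fixed, TIF1g varied) and
#' normalizes the peak pS24n (or its area under the curve) to the ratio-0
#' value, yielding the dimensionless relative-signal curve that fold-change
#' data are fitted against.
#'
#' @param ratios TIF1g/Smad4 ratios (>= 0).
#' @param variant Mechanism, default `"INTEGRATED"`.
#' @param protocol Stimulation protocol, default sustained 10 nM.
#' @param smad4_total Smad4 total (nM), default 50.
#' @param statistic `"peak"` (default) or `"auc"`.
#' @param params Parameter set.
#' @param t_grid Output time grid (s).
#' @param opts Solver options.
#' @return A data.frame of class `tgf_relcurve` with columns `ratio`,
#'   `signal` (nM or nM*s) and `relative` (dimensionless, 1 at ratio 0).
#' @export
predict_relative_signal <- function(ratios, variant = "INTEGRATED",
                                    protocol = stimulus_protocol("sustained",
                                                                 concentration = 10),
                                    smad4_total = 50,
                                    statistic = c("peak", "auc"),
                                    params = default_parameters(),
                                    t_grid = .default_scan_grid(),
                                    opts = solver_options()) {
  statistic <- match.arg(statistic)
  if (any(ratios < 0)) stop("ratios must be >= 0", call. = FALSE)
  variant <- as_variant(variant)
  all_ratios <- sort(unique(c(0, ratios)))
  val <- numeric(length(all_ratios))
  for (i in seq_along(all_ratios)) {
    sys <- build_model(variant, params,
                       init = c(TIF1g_n = all_ratios[i] * smad4_total,
                                S4c = smad4_total))
    traj <- simulate_system(sys, protocol, t_grid, opts)
    y <- readout(traj, "pS24n")
    val[i] <- if (statistic == "peak") max(y) else
      sum(diff(traj$time) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }
  base <- val[all_ratios == 0]
  if (base <= 0)
    stop("zero baseline signal at ratio 0; cannot normalize", call. = FALSE)
  keep <- all_ratios %in% ratios
  out <- data.frame(ratio = all_ratios[keep], signal = val[keep],
                    relative = val[keep] / base)
  class(out) <- c("tgf_relcurve", "data.frame")
  attr(out, "statistic") <- statistic
  attr(out, "baseline") <- base
  out
}

.curve_at <- function(curve, ratios) {
  stopifnot(is.data.frame(curve), all(c("ratio", "relative") %in% names(curve)))
  if (nrow(curve) == 1) return(rep(curve$relative, length(ratios)))
  # piecewise-linear interpolation: shape-preserving for a monotone curve,
  # constant extrapolation beyond the grid
  stats::approx(curve$ratio, curve$relative, xout = ratios, rule = 2,
                ties = "ordered")$y
}

#' Fit the transcription scaling of fold-change data to a predicted curve
#'
#' Least-squares affine map `fold_change ~ a * curve(ratio) + b` (or pure
#' scaling with `b = 0`), with the curve evaluated at each data ratio by
#' piecewise-linear interpolation. Optional inverse-variance weights `1/sd^2`.
#'
#' @param data A ratio dataset: data.frame with at least `ratio` and
#'   `fold_change` (and `sd` if `weighted`); see [read_ratio_dataset()].
#' @param curve A relative-signal curve from [predict_relative_signal()] (or
#'   any data.frame with `ratio` and `relative`).
#' @param form `"affine"` (scale + offset) or `"scale"` (offset fixed at 0).
#' @param weighted Use weights `1/sd^2`.
#' @return A `tgf_fit` list: `a`, `b`, `rss`, `residuals`, `fitted`,
#'   `n`, `form`, `singular` flag.
#' @export
fit_scaling <- function(data, curve, form = c("affine", "scale"),
                        weighted = FALSE) {
  form <- match.arg(form)
  stopifnot(is.data.frame(data), all(c("ratio", "fold_change") %in% names(data)))
  if (any(data$ratio < 0)) stop("ratios must be >= 0", call. = FALSE)
  if (length(unique(data$ratio)) < 3)
    stop("need at least 3 distinct ratios to fit", call. = FALSE)
  x <- .curve_at(curve, data$ratio)
  y <- data$fold_change
  w <- rep(1, length(y))
  if (weighted) {
    if (!"sd" %in% names(data)) stop("weighted fit needs an sd column", call. = FALSE)
    if (any(data$sd <= 0)) stop("weights require positive sd", call. = FALSE)
    w <- 1 / data$sd^2
  }
  X <- if (form == "affine") cbind(curve = x, offset = 1) else cbind(curve = x)
  fit <- stats::lm.wfit(X, y, w)
  singular <- fit$rank < ncol(X)
  if (singular && form == "affine" && stats::sd(x) == 0)
    stop("rank deficiency: curve is constant over the data ratios", call. = FALSE)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  res <- y - drop(X %*% coefs)
  structure(list(a = unname(coefs["curve"]),
                 b = if (form == "affine") unname(coefs["offset"]) else 0,
                 rss = sum(w * res^2),
                 residuals = res,
                 fitted = drop(X %*% coefs),
                 n = length(y), form = form, weighted = weighted,
                 singular = singular),
            class = "tgf_fit")
}

#' @export
print.tgf_fit <- function(x, ...) {
  cat("Transcription-scaling fit (", x$form, "): a = ", format(x$a),
      ", b = ", format(x$b), ", RSS = ", format(x$rss),
      " over ", x$n, " points\n", sep = "")
  invisible(x)
}
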