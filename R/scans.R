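# The computational experiments: TIF1g concentration scans per variant,
# one-at-a-time kinetic sensitivity, dose/duration responses, ratio x duration
# response surfaces, and pulsed-versus-sustained stimulation. Every scan is a
# deterministic pipeline: same configuration, same numbers.

new_scan <- function(summary, axis, variant, protocol, curves = NULL, extra = list()) {
  structure(c(list(summary = summary, axis = axis, variant = variant,
                   protocol = protocol, curves = curves), extra),
            class = "tgf_scan")
}

#' @export
print.tgf_scan <- function(x, ...) {
  cat("Scan over", x$axis, "(", nrow(x$summary), "points ), variant",
      x$variant, "\n")
  print(x$summary, ...)
  invisible(x)
}

.default_scan_grid <- function() seq(0, 12 * 3600, by = 120)

.run_point <- function(system, protocol, t_grid, opts) {
  traj <- simulate_system(system, protocol, t_grid, opts)
  pk <- peak_response(traj, "pS24n")
  list(traj = traj, peak = pk$value, t_peak = pk$time)
}

#' Scan the pS24n response over TIF1g concentrations
#'
#' Simulates one variant at a fixed sustained ligand input for each total
#' TIF1g concentration, each point from its own ligand-free pre-equilibrated
#' state, and summarizes the peak nuclear phospho-Smad2/Smad4 signal.
#'
#' @param variant Mechanism string or `tgf_variant`.
#' @param tif1g_grid TIF1g total concentrations (nM), default 0-50 nM.
#' @param ligand Sustained TGF-beta input (nM), default 10.
#' @param params Parameter set.
#' @param t_grid Output time grid (s).
#' @param opts Solver options.
#' @param keep_curves Keep the full pS24n curve per grid point.
#' @return A `tgf_scan` with one summary row per grid point (tif1g, peak
#'   pS24n in nM, time of peak in s).
#' @export
scan_tif1g <- function(variant = "INTEGRATED",
                       tif1g_grid = c(0, 1, 2, 5, 10, 20, 30, 40, 50),
                       ligand = 10, params = default_parameters(),
                       t_grid = .default_scan_grid(),
                       opts = solver_options(), keep_curves = TRUE) {
  variant <- as_variant(variant)
  if (is.unsorted(tif1g_grid, strictly = TRUE))
    stop("tif1g_grid must be strictly increasing", call. = FALSE)
  protocol <- stimulus_protocol("sustained", concentration = ligand)
  rows <- list(); curves <- list()
  for (i in seq_along(tif1g_grid)) {
    g <- tif1g_grid[i]
    sys <- build_model(variant, params, init = c(TIF1g_n = g))
    pt <- tryCatch(.run_point(sys, protocol, t_grid, opts),
                   error = function(e) stop("solver failure at TIF1g = ", g,
                                            " nM: ", conditionMessage(e),
                                            call. = FALSE))
    rows[[i]] <- data.frame(tif1g = g, peak_pS24n = pt$peak, t_peak = pt$t_peak)
    if (keep_curves)
      curves[[i]] <- data.frame(tif1g = g, time = pt$traj$time,
                                pS24n = readout(pt$traj, "pS24n"))
  }
  new_scan(do.call(rbind, rows), axis = "tif1g", variant = variant$mechanism,
           protocol = protocol,
           curves = if (keep_curves) do.call(rbind, curves))
}

#' One-at-a-time sensitivity of the pS24n response to a kinetic constant
#'
#' Rescales a single rate constant by each multiplier, re-simulates the model
#' at a sustained ligand input, and reports the spread of peak pS24n. The
#' scalar sensitivity index is (max - min) peak over the multiplier grid
#' divided by the peak at multiplier 1.
#'
#' @param parameter Parameter symbol, e.g. `"k_in_S4ub"`.
#' @param multipliers Positive multipliers, default `c(0.25, 0.5, 1, 2, 4)`.
#' @param fam_level FAM/USP9x concentration (nM), default 1.
#' @param variant Mechanism, default `"INTEGRATED"`.
#' @param tif1g TIF1g total (nM) at which sensitivity is probed, default 10
#'   (the mid-range TIF1g dose).
#' @param ligand Sustained TGF-beta input (nM), default 10.
#' @inheritParams scan_tif1g
#' @return A `tgf_scan`; the extra element `sensitivity_index` holds the
#'   scalar index.
#' @export
sensitivity_scan <- function(parameter, multipliers = c(0.25, 0.5, 1, 2, 4),
                             fam_level = 1, variant = "INTEGRATED",
                             tif1g = 10, ligand = 10,
                             params = default_parameters(),
                             t_grid = .default_scan_grid(),
                             opts = solver_options()) {
  variant <- as_variant(variant)
  if (!parameter %in% names(params))
    stop("unknown parameter symbol: ", parameter, call. = FALSE)
  if (any(multipliers <= 0)) stop("multipliers must be > 0", call. = FALSE)
  protocol <- stimulus_protocol("sustained", concentration = ligand)
  init <- c(TIF1g_n = tif1g)
  if (variant$fam_included) init["FAM"] <- fam_level
  rows <- list()
  for (i in seq_along(multipliers)) {
    m <- multipliers[i]
    p2 <- do.call(set_parameters,
                  stats::setNames(list(params, unname(params[[parameter]]) * m),
                                  c("", parameter)))
    sys <- build_model(variant, p2, init = init)
    pt <- .run_point(sys, protocol, t_grid, opts)
    rows[[i]] <- data.frame(parameter = parameter, multiplier = m,
                            peak_pS24n = pt$peak, t_peak = pt$t_peak)
  }
  summary <- do.call(rbind, rows)
  ref <- summary$peak_pS24n[summary$multiplier == 1]
  if (length(ref) == 0) ref <- stats::median(summary$peak_pS24n)
  idx <- (max(summary$peak_pS24n) - min(summary$peak_pS24n)) / ref
  new_scan(summary, axis = "multiplier", variant = variant$mechanism,
           protocol = protocol,
           extra = list(sensitivity_index = idx, parameter = parameter,
                        fam_level = fam_level, tif1g = tif1g))
}

#' Peak pS24n as a function of TGF-beta dose
#'
#' @param doses Ligand concentrations (nM).
#' @param variant Mechanism, default `"INTEGRATED"`.
#' @param depletion Simulate with ligand depletion.
#' @param tif1g TIF1g total (nM), default 10.
#' @inheritParams scan_tif1g
#' @return A `tgf_scan` with peak pS24n per dose.
#' @export
dose_response <- function(doses = c(0, 0.1, 1, 5, 10, 50), variant = "INTEGRATED",
                          depletion = FALSE, tif1g = 10,
                          params = default_parameters(),
                          t_grid = .default_scan_grid(),
                          opts = solver_options()) {
  variant <- as_variant(variant)
  if (any(doses < 0)) stop("doses must be >= 0", call. = FALSE)
  variant$ligand_depletion <- isTRUE(depletion)
  sys <- build_model(variant, params, init = c(TIF1g_n = tif1g))
  y0 <- equilibrate(sys, opts)
  rows <- list()
  for (i in seq_along(doses)) {
    protocol <- stimulus_protocol("sustained", concentration = doses[i],
                                  depletion = depletion)
    traj <- simulate_system(sys, protocol, t_grid, opts, y0 = y0)
    pk <- peak_response(traj, "pS24n")
    rows[[i]] <- data.frame(dose = doses[i], peak_pS24n = pk$value,
                            t_peak = pk$time)
  }
  new_scan(do.call(rbind, rows), axis = "dose", variant = variant$mechanism,
           protocol = stimulus_protocol("sustained", concentration = max(doses),
                                        depletion = depletion))
}

#' Maximum pS24n as a function of stimulation duration
#'
#' Applies a finite window of 10 nM TGF-beta and records the maximum pS24n
#' reached at any time (a trailing margin after ligand removal is simulated so
#' late maxima are not cut off).
#'
#' @param durations Stimulus durations (s), default logarithmic from 5 min to
#'   48 h.
#' @param tif1g_levels TIF1g totals (nM) to cross with duration.
#' @param ligand Ligand concentration during the window (nM).
#' @param variant Mechanism, default `"INTEGRATED"`.
#' @param margin Post-stimulus horizon (s) over which the maximum is still
#'   tracked.
#' @inheritParams scan_tif1g
#' @return A `tgf_scan` with max pS24n per (duration, tif1g) pair.
#' @export
duration_response <- function(durations = round(exp(seq(log(300), log(48 * 3600),
                                                        length.out = 9))),
                              tif1g_levels = c(0, 10, 25, 50),
                              ligand = 10, variant = "INTEGRATED",
                              margin = 2 * 3600,
                              params = default_parameters(),
                              opts = solver_options()) {
  variant <- as_variant(variant)
  if (any(durations <= 0)) stop("durations must be > 0", call. = FALSE)
  rows <- list(); r <- 0
  for (g in tif1g_levels) {
    sys <- build_model(variant, params, init = c(TIF1g_n = g))
    y0 <- equilibrate(sys, opts)
    for (d in durations) {
      protocol <- stimulus_protocol("window", concentration = ligand,
                                    t_on = 0, t_off = d)
      t_max <- d + margin
      t_grid <- sort(unique(c(seq(0, t_max, length.out = 400), d)))
      traj <- simulate_system(sys, protocol, t_grid, opts, y0 = y0)
      pk <- peak_response(traj, "pS24n")
      r <- r + 1
      rows[[r]] <- data.frame(duration = d, tif1g = g,
                              max_pS24n = pk$value, t_peak = pk$time)
    }
  }
  new_scan(do.call(rbind, rows), axis = "duration x tif1g",
           variant = variant$mechanism,
           protocol = stimulus_protocol("window", concentration = ligand,
                                        t_off = max(durations)))
}

#' Normalized response surface over TIF1g/Smad4 ratio and stimulation duration
#'
#' Smad4 total is held at its default (50 nM) and the ratio axis varies the
#' TIF1g total. Each cell holds the maximum of the requested readout for that
#' (ratio, duration) pair; the surface is scaled so its global maximum is
#' 100 percent.
#'
#' @param ratio_grid TIF1g/Smad4 ratios (dimensionless).
#' @param duration_grid Stimulus durations (s).
#' @param readout_name `"pS24n"` or `"pS2nTIF1g"`.
#' @param smad4_total Smad4 total (nM) the ratio is referenced to.
#' @param ligand Ligand concentration during the window (nM).
#' @param variant Mechanism, default `"INTEGRATED"`.
#' @param margin Post-stimulus horizon (s).
#' @inheritParams scan_tif1g
#' @return A list of class `tgf_surface`: `surface` (ratio x duration matrix,
#'   percent of maximum), `ratio`, `duration`, `readout`, `max_value` (the
#'   unnormalized global maximum, nM).
#' @export
response_surface <- function(ratio_grid = c(0, 0.2, 0.5, 1, 2),
                             duration_grid = c(900, 3600, 3 * 3600, 12 * 3600,
                                               48 * 3600),
                             readout_name = c("pS24n", "pS2nTIF1g"),
                             smad4_total = 50, ligand = 10,
                             variant = "INTEGRATED", margin = 2 * 3600,
                             params = default_parameters(),
                             opts = solver_options()) {
  readout_name <- match.arg(readout_name)
  variant <- as_variant(variant)
  surf <- matrix(NA_real_, length(ratio_grid), length(duration_grid),
                 dimnames = list(ratio = format(ratio_grid),
                                 duration = format(duration_grid)))
  for (i in seq_along(ratio_grid)) {
    g <- ratio_grid[i] * smad4_total
    sys <- build_model(variant, params,
                       init = c(TIF1g_n = g, S4c = smad4_total))
    y0 <- equilibrate(sys, opts)
    for (j in seq_along(duration_grid)) {
      d <- duration_grid[j]
      protocol <- stimulus_protocol("window", concentration = ligand,
                                    t_on = 0, t_off = d)
      t_max <- d + margin
      t_grid <- sort(unique(c(seq(0, t_max, length.out = 400), d)))
      traj <- simulate_system(sys, protocol, t_grid, opts, y0 = y0)
      surf[i, j] <- peak_response(traj, readout_name)$value
    }
  }
  mx <- max(surf)
  if (mx <= 0) {
    warning("degenerate all-zero surface; not normalized")
    pct <- surf
  } else {
    pct <- surf / mx * 100
  }
  structure(list(surface = pct, ratio = ratio_grid, duration = duration_grid,
                 readout = readout_name, max_value = mx,
                 variant = variant$mechanism),
            class = "tgf_surface")
}

#' @export
print.tgf_surface <- function(x, ...) {
  cat("Response surface of", x$readout, "(% of max", format(x$max_value),
      "nM), variant", x$variant, "\n")
  print(round(x$surface, 1), ...)
  invisible(x)
}

#' Compare sustained and pulsed TGF-beta stimulation
#'
#' Simulates the pS24n response to sustained ligand and to pulse trains, and
#' classifies each pulsed response as sustained-like or decaying by the ratio
#' of its inter-pulse troughs to the sustained curve at the same times.
#'
#' @param tif1g TIF1g total (nM), default 0.
#' @param ligand Ligand concentration (nM), default 10.
#' @param intervals Pulse periods (s), default 30 min and 3 h.
#' @param pulse_width Pulse duration (s), default 5 min.
#' @param t_max Simulation horizon (s), default 12 h.
#' @param trough_threshold Fraction of the sustained response the troughs must
#'   retain (after the first period) to call the outcome sustained-like;
#'   default 0.5.
#' @param variant Mechanism, default `"INTEGRATED"`.
#' @inheritParams scan_tif1g
#' @return A `tgf_scan`; summary has one row per protocol with
#'   `trough_ratio` and `sustained_like`; `curves` holds the full responses.
#' @export
pulse_comparison <- function(tif1g = 0, ligand = 10,
                             intervals = c(1800, 10800), pulse_width = 300,
                             t_max = 12 * 3600, trough_threshold = 0.5,
                             variant = "INTEGRATED",
                             params = default_parameters(),
                             opts = solver_options()) {
  variant <- as_variant(variant)
  sys <- build_model(variant, params, init = c(TIF1g_n = tif1g))
  y0 <- equilibrate(sys, opts)
  t_grid <- seq(0, t_max, by = 60)
  sust <- simulate_system(sys, stimulus_protocol("sustained",
                                                 concentration = ligand),
                          t_grid, opts, y0 = y0)
  ys <- readout(sust, "pS24n")
  curves <- list(data.frame(protocol = "sustained", time = sust$time, pS24n = ys))
  rows <- list(data.frame(protocol = "sustained", interval = NA_real_,
                          peak_pS24n = max(ys), trough_ratio = 1,
                          sustained_like = TRUE))
  for (iv in intervals) {
    prot <- stimulus_protocol("pulse_train", concentration = ligand,
                              pulse_width = pulse_width, interval = iv)
    traj <- simulate_system(sys, prot, t_grid, opts, y0 = y0)
    yp <- readout(traj, "pS24n")
    ysx <- stats::approx(sust$time, ys, xout = traj$time, rule = 2)$y
    after <- traj$time >= iv & ysx > 0
    ratio <- min(yp[after] / ysx[after])
    lab <- sprintf("pulses_%gmin", iv / 60)
    rows[[length(rows) + 1]] <- data.frame(protocol = lab, interval = iv,
                                           peak_pS24n = max(yp),
                                           trough_ratio = ratio,
                                           sustained_like = ratio >= trough_threshold)
    curves[[length(curves) + 1]] <- data.frame(protocol = lab,
                                               time = traj$time, pS24n = yp)
  }
  new_scan(do.call(rbind, rows), axis = "protocol",
           variant = variant$mechanism,
           protocol = stimulus_protocol("sustained", concentration = ligand),
           curves = do.call(rbind, curves),
           extra = list(tif1g = tif1g, trough_threshold = trough_threshold))
}
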