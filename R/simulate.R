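# Stiff integration of a model system under a stimulation protocol. The
# integration is restarted at every protocol discontinuity so ligand edges are
# never smeared by the step controller, and results are reported on the user
# grid through the solver's dense output.

#' Solver options
#'
#' @param rtol Relative tolerance (default 1e-8).
#' @param atol Absolute tolerance in nM (default 1e-12).
#' @param max_step Maximum internal step (s).
#' @param method A stiff-capable adaptive method understood by
#'   [deSolve::ode()]; `"lsoda"` switches automatically between stiff and
#'   non-stiff regimes.
#' @return A `tgf_solver_options` list.
#' @export
solver_options <- function(rtol = 1e-8, atol = 1e-12, max_step = Inf,
                           method = "lsoda") {
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive", call. = FALSE)
  structure(list(rtol = rtol, atol = atol, max_step = max_step, method = method),
            class = "tgf_solver_options")
}

# fast rhs closure for deSolve (no per-call validation)
.make_deriv <- function(system) {
  mmat <- system$mmat
  k <- system$k
  kin_idx <- system$kin_idx
  kin_pow <- system$kin_pow
  lig <- system$ligand_driven
  nrx <- length(k)
  function(t, y, parms) {
    y <- pmax(y, 0)
    flux <- k
    for (j in seq_len(nrx)) {
      idx <- kin_idx[[j]]
      if (length(idx) > 0) flux[j] <- flux[j] * prod(y[idx] ^ kin_pow[[j]])
      if (lig[j]) flux[j] <- flux[j] * parms$ligand
    }
    list(drop(mmat %*% flux))
  }
}

.integrate_segment <- function(deriv, y0, times, ligand, opts) {
  if (length(times) == 1) {
    out <- matrix(y0, nrow = 1, dimnames = list(NULL, names(y0)))
    return(list(y = out, times = times, steps = 0L))
  }
  sol <- deSolve::ode(y = y0, times = times, func = deriv,
                      parms = list(ligand = ligand),
                      method = opts$method, rtol = opts$rtol, atol = opts$atol,
                      hmax = if (is.finite(opts$max_step)) opts$max_step else NULL)
  if (attr(sol, "istate")[1] < 0)
    stop("solver failure near t = ", format(utils::tail(sol[, 1], 1)), " s",
         call. = FALSE)
  steps <- attr(sol, "istate")[3]
  list(y = sol[, -1, drop = FALSE], times = sol[, 1], steps = steps)
}

#' Equilibrate a model without ligand
#'
#' Integrates the ligand-free system until `max |dy/dt| < tol` (default 1e-10
#' nM/s) and returns the steady state used as the pre-stimulation condition.
#'
#' @param system A `tgf_model`.
#' @param opts Solver options.
#' @param tol Steady-state tolerance on the derivative (nM/s).
#' @param t_block Integration block length (s); blocks are repeated (up to 50)
#'   until the tolerance is met.
#' @return Named steady-state vector (nM).
#' @export
equilibrate <- function(system, opts = solver_options(), tol = 1e-10,
                        t_block = 2e6) {
  y <- stats::setNames(system$species$initial, system$species$name)
  if ("TGFb" %in% names(y)) y[["TGFb"]] <- 0
  deriv <- .make_deriv(system)
  for (i in 1:50) {
    res <- max(abs(model_rhs(system, y, 0, ligand = 0)))
    if (res < tol) return(y)
    seg <- .integrate_segment(deriv, y, c(0, t_block), ligand = 0, opts)
    y <- pmax(seg$y[nrow(seg$y), ], 0)
  }
  stop("failed to reach a ligand-free steady state (residual ",
       format(res), " nM/s)", call. = FALSE)
}

#' Simulate a model under a stimulation protocol
#'
#' The system is first pre-equilibrated without ligand (unless `y0` is given),
#' then integrated with a stiff-capable adaptive solver. Integration restarts
#' at every protocol discontinuity, and those edge times are inserted into the
#' output grid.
#'
#' @param system A `tgf_model`.
#' @param protocol A `tgf_protocol`; its `depletion` flag must match the model
#'   variant's `ligand_depletion`.
#' @param t_grid Strictly increasing output times starting at 0 (s).
#' @param opts Solver options from [solver_options()].
#' @param y0 Optional pre-equilibrated initial state (nM); computed by
#'   [equilibrate()] when omitted.
#' @return A `tgf_trajectory`: time grid, species matrix (nM), protocol echo
#'   and solver diagnostics.
#' @export
simulate_system <- function(system, protocol = stimulus_protocol("sustained"),
                            t_grid = seq(0, 6 * 3600, by = 60),
                            opts = solver_options(), y0 = NULL) {
  stopifnot(inherits(system, "tgf_model"), inherits(protocol, "tgf_protocol"))
  if (t_grid[1] != 0 || is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing and start at 0", call. = FALSE)
  if (protocol$depletion != system$variant$ligand_depletion) {
    if (protocol$depletion)
      stop("depletion requested but the model has no depletable ligand species",
           call. = FALSE)
    stop("the model tracks ligand depletion; use a depleting protocol",
         call. = FALSE)
  }
  if (is.null(y0)) y0 <- equilibrate(system, opts)
  .check_state(system, y0)

  t_max <- max(t_grid)
  edges <- protocol_edges(protocol, t_max)
  breaks <- sort(unique(c(0, edges$on, edges$off, t_max)))
  breaks <- breaks[breaks >= 0 & breaks <= t_max]
  times_out <- sort(unique(c(t_grid, breaks)))

  deriv <- .make_deriv(system)
  y <- stats::setNames(as.numeric(y0), system$species$name)
  rows <- list()
  total_steps <- 0L
  for (s in seq_len(length(breaks) - 1)) {
    a <- breaks[s]; b <- breaks[s + 1]
    if (protocol$depletion && a %in% edges$on)
      y[["TGFb"]] <- protocol$concentration
    lig <- if (protocol$depletion) 0 else
      ligand_value(protocol, (a + b) / 2)
    seg_times <- times_out[times_out >= a & times_out <= b]
    if (seg_times[1] > a) seg_times <- c(a, seg_times)
    seg <- .integrate_segment(deriv, y, seg_times, lig, opts)
    total_steps <- total_steps + seg$steps
    keep <- seg$times %in% times_out & seg$times < b
    rows[[s]] <- seg$y[keep, , drop = FALSE]
    y <- seg$y[nrow(seg$y), ]
    attr(rows[[s]], "times") <- seg$times[keep]
  }
  mat <- do.call(rbind, c(rows, list(matrix(y, nrow = 1))))
  times <- c(unlist(lapply(rows, attr, "times")), t_max)
  colnames(mat) <- system$species$name

  low <- min(mat)
  if (low < -1e-6)
    stop("integration produced concentrations below -1e-6 nM (min ",
         format(low), "); tighten solver tolerances", call. = FALSE)
  if (low < -1e-9)
    warning("clamping small negative concentrations (min ", format(low), " nM)")
  mat[mat < 0] <- 0

  structure(list(time = times, mat = mat, protocol = protocol,
                 variant = system$variant$mechanism,
                 conservation = system$conservation,
                 diagnostics = list(steps = total_steps,
                                    segments = length(breaks) - 1),
                 opts = opts),
            class = "tgf_trajectory")
}

#' @export
print.tgf_trajectory <- function(x, ...) {
  cat("Trajectory (", x$variant, "): ", length(x$time), " time points over ",
      max(x$time) / 3600, " h, ", ncol(x$mat), " species\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.tgf_trajectory <- function(x, ...) {
  data.frame(time = rep(x$time, ncol(x$mat)),
             species = rep(colnames(x$mat), each = length(x$time)),
             value = as.vector(x$mat),
             stringsAsFactors = FALSE)
}

#' Extract a readout time series from a trajectory
#'
#' `pS24n` (the transcription-competent pool: nuclear phospho-Smad2/Smad4
#' complexes not bound to TIF1g) and `pS2nTIF1g` are the two readouts of
#' interest; any other species name is also accepted.
#'
#' @param traj A `tgf_trajectory`.
#' @param name Species / readout name.
#' @return Numeric series aligned to `traj$time`.
#' @export
readout <- function(traj, name = "pS24n") {
  stopifnot(inherits(traj, "tgf_trajectory"))
  if (!name %in% colnames(traj$mat))
    stop("unknown readout name: ", name, call. = FALSE)
  stats::setNames(traj$mat[, name], NULL)
}

#' Peak of a readout
#'
#' @param traj A `tgf_trajectory`.
#' @param name Readout name as in [readout()].
#' @return A list with `value` (nM) and `time` (s, first time the maximum is
#'   attained).
#' @export
peak_response <- function(traj, name = "pS24n") {
  y <- readout(traj, name)
  i <- which.max(y)
  list(value = y[i], time = traj$time[i])
}

#' Conservation drift along a trajectory
#'
#' @param system The `tgf_model` the trajectory came from.
#' @param traj A `tgf_trajectory`.
#' @return Named vector of maximal relative deviations of each conserved total
#'   from its initial value (0 for moieties whose total is 0).
#' @export
conservation_drift <- function(system, traj) {
  tot0 <- conserved_totals(system, traj$mat[1, ])
  drift <- rep(0, length(tot0))
  names(drift) <- names(tot0)
  for (i in seq_along(traj$time)) {
    tot <- conserved_totals(system, traj$mat[i, ])
    rel <- ifelse(tot0 > 0, abs(tot - tot0) / tot0, abs(tot - tot0))
    drift <- pmax(drift, rel)
  }
  drift
}
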