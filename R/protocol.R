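# Time-dependent extracellular TGF-beta inputs. Without ligand depletion the
# protocol clamps the extracellular concentration; with depletion it only
# places boluses (the ligand then lives as a state variable consumed by
# receptor-complex formation).

#' Define a TGF-beta stimulation protocol
#'
#' @param kind `"none"`, `"sustained"` (constant ligand from `t_on` on),
#'   `"window"` (ligand between `t_on` and `t_off`), or `"pulse_train"`
#'   (`n_pulses` pulses of `pulse_width` seconds starting every `interval`
#'   seconds from `t_on`).
#' @param concentration Ligand concentration (nM) while the stimulus is on.
#' @param t_on,t_off Window boundaries (s); `t_off > t_on`.
#' @param pulse_width,interval,n_pulses Pulse geometry (s, s, count);
#'   `interval >= pulse_width` so pulses are disjoint, `n_pulses = Inf` fills
#'   the horizon.
#' @param depletion If `TRUE` the protocol only sets boluses and the ligand is
#'   consumed by binding; requires a model built with `ligand_depletion`.
#' @return A `tgf_protocol` object.
#' @export
stimulus_protocol <- function(kind = c("sustained", "none", "window", "pulse_train"),
                              concentration = 10,
                              t_on = 0, t_off = NULL,
                              pulse_width = 300, interval = 1800, n_pulses = Inf,
                              depletion = FALSE) {
  kind <- match.arg(kind)
  if (concentration < 0) stop("concentration must be >= 0", call. = FALSE)
  if (kind == "window") {
    if (is.null(t_off) || t_off <= t_on)
      stop("window protocol needs t_off > t_on", call. = FALSE)
  }
  if (kind == "pulse_train") {
    if (pulse_width <= 0) stop("pulse_width must be > 0", call. = FALSE)
    if (interval < pulse_width)
      stop("interval must be >= pulse_width (pulses are disjoint)", call. = FALSE)
    if (n_pulses < 1) stop("n_pulses must be >= 1", call. = FALSE)
  }
  structure(list(kind = kind, concentration = concentration,
                 t_on = t_on, t_off = t_off,
                 pulse_width = pulse_width, interval = interval,
                 n_pulses = n_pulses, depletion = isTRUE(depletion)),
            class = "tgf_protocol")
}

#' @export
print.tgf_protocol <- function(x, ...) {
  cat("Stimulus:", x$kind, "at", x$concentration, "nM",
      if (x$depletion) "(depleting)", "\n")
  invisible(x)
}

# discontinuity times of the input on [0, t_max]; first column on-edges
protocol_edges <- function(protocol, t_max) {
  p <- protocol
  on <- off <- numeric(0)
  if (p$kind == "sustained") {
    on <- p$t_on
  } else if (p$kind == "window") {
    on <- p$t_on; off <- p$t_off
  } else if (p$kind == "pulse_train") {
    n <- if (is.finite(p$n_pulses)) p$n_pulses
         else max(1, ceiling((t_max - p$t_on) / p$interval) + 1)
    starts <- p$t_on + (seq_len(n) - 1) * p$interval
    starts <- starts[starts <= t_max]
    on <- starts
    off <- starts + p$pulse_width
  }
  list(on = on[on >= 0 & on <= t_max], off = off[off >= 0 & off <= t_max])
}

#' Prescribed ligand concentration at a time
#'
#' Without depletion this is the input clamp the integrator sees; with
#' depletion the ligand is a state variable and its current value is read from
#' `state` (the protocol then only determines bolus times).
#'
#' @param protocol A `tgf_protocol`.
#' @param t Time or vector of times (s).
#' @param state Optional state vector of a depletion-variant model.
#' @return Ligand concentration(s), nM.
#' @export
ligand_value <- function(protocol, t, state = NULL) {
  p <- protocol
  if (p$depletion && !is.null(state)) {
    if (!"TGFb" %in% names(state))
      stop("state has no depletable ligand species", call. = FALSE)
    return(rep(unname(state[["TGFb"]]), length(t)))
  }
  active <- switch(p$kind,
    none = rep(FALSE, length(t)),
    sustained = t >= p$t_on,
    window = t >= p$t_on & t < p$t_off,
    pulse_train = {
      k <- floor((t - p$t_on) / p$interval)
      within <- (t - p$t_on) - k * p$interval < p$pulse_width
      t >= p$t_on & k < p$n_pulses & within
    })
  ifelse(active, p$concentration, 0)
}
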