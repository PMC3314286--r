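# Shared fixtures: short horizons keep the suite fast; peaks of the 10 nM
# sustained response occur well before 4 h in every variant.

short_grid <- function(hours = 4, dt = 180) seq(0, hours * 3600, by = dt)

sustained10 <- function() stimulus_protocol("sustained", concentration = 10)

peak_at <- function(mechanism, tif1g = NULL, params = default_parameters(),
                    t_grid = short_grid()) {
  sys <- if (is.null(tif1g)) build_model(mechanism, params)
         else build_model(mechanism, params, init = c(TIF1g_n = tif1g))
  max(readout(simulate_system(sys, sustained10(), t_grid), "pS24n"))
}

# analytic stand-in curve for fit tests that do not need ODE simulations
toy_curve <- function(ratios = c(0, 0.25, 0.5, 1, 1.5, 2)) {
  data.frame(ratio = ratios, relative = exp(-1.2 * ratios))
}
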