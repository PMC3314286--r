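test_that("the ligand-free system settles to a genuine steady state", {
  sys <- build_model("INTEGRATED", init = c(TIF1g_n = 10))
  y0 <- equilibrate(sys)
  expect_lt(max(abs(model_rhs(sys, y0, 0, ligand = 0))), 1e-10)
  # no phosphorylation without ligand: the basal signal is zero
  expect_equal(unname(y0[["pS24n"]]), 0, tolerance = 1e-12)
})

test_that("without stimulation the trajectory stays at the basal state", {
  sys <- build_model("INTEGRATED", init = c(TIF1g_n = 10))
  traj <- simulate_system(sys, stimulus_protocol("none"), short_grid(2))
  expect_true(all(abs(readout(traj, "pS24n")) < 1e-9))
  expect_identical(unname(readout(traj, "pS24n")[1]), 0)
  # trajectory invariants
  expect_true(all(diff(traj$time) > 0))
  expect_true(all(traj$mat >= 0))
  expect_identical(ncol(traj$mat), nrow(model_species(sys)))
})

test_that("readouts resolve species and reject unknown names", {
  sys <- build_model("INTEGRATED", init = c(TIF1g_n = 0))
  traj <- simulate_system(sys, sustained10(), short_grid(1))
  expect_identical(unname(readout(traj, "pS24n")[1]), 0)
  expect_true(all(readout(traj, "pS2nTIF1g") == 0)) # empty TIF1g pool
  expect_error(readout(traj, "pSBogus"), "unknown readout")
})

test_that("peak_response returns the first attained global maximum", {
  sys <- build_model("INTEGRATED", init = c(TIF1g_n = 10))
  flat <- simulate_system(sys, stimulus_protocol("none"), short_grid(1))
  pk <- peak_response(flat, "pS24n")
  expect_identical(pk$value, 0)
  expect_identical(pk$time, 0)
  # over a short horizon the response is still rising: max at the final time
  rising <- simulate_system(sys, sustained10(), seq(0, 1200, by = 60))
  pk2 <- peak_response(rising, "pS24n")
  expect_identical(pk2$time, 1200)
  # grid refinement barely moves the peak
  coarse <- simulate_system(sys, sustained10(), seq(0, 4 * 3600, by = 600))
  fine <- simulate_system(sys, sustained10(), seq(0, 4 * 3600, by = 60))
  expect_equal(peak_response(coarse, "pS24n")$value,
               peak_response(fine, "pS24n")$value, tolerance = 1e-3)
})

test_that("protocol discontinuities appear exactly in the output grid", {
  sys <- build_model("INTEGRATED", init = c(TIF1g_n = 5))
  w <- stimulus_protocol("window", concentration = 10, t_on = 0, t_off = 1234.5)
  traj <- simulate_system(sys, w, seq(0, 7200, by = 600))
  expect_true(1234.5 %in% traj$time)
  p <- stimulus_protocol("pulse_train", concentration = 10,
                         pulse_width = 300, interval = 1800, n_pulses = 3)
  traj2 <- simulate_system(sys, p, seq(0, 7200, by = 600))
  expect_true(all(c(0, 300, 1800, 2100, 3600, 3900) %in% traj2$time))
})

test_that("conserved totals drift less than 1e-6 along a stimulated trajectory", {
  sys <- build_model("INTEGRATED", init = c(TIF1g_n = 25))
  traj <- simulate_system(sys, sustained10(), short_grid(4))
  expect_lt(max(conservation_drift(sys, traj)), 1e-6)
})

test_that("halving the tolerances leaves the final state essentially unchanged", {
  sys <- build_model("INTEGRATED", init = c(TIF1g_n = 10))
  y0 <- equilibrate(sys)
  tg <- seq(0, 3600, by = 300)
  t1 <- simulate_system(sys, sustained10(), tg,
                        solver_options(rtol = 1e-6, atol = 1e-10), y0 = y0)
  t2 <- simulate_system(sys, sustained10(), tg,
                        solver_options(rtol = 5e-7, atol = 5e-11), y0 = y0)
  rel <- abs(t1$mat[nrow(t1$mat), ] - t2$mat[nrow(t2$mat), ]) /
    pmax(abs(t2$mat[nrow(t2$mat), ]), 1e-6)
  expect_lt(max(rel), 10 * 1e-6)
})

test_that("contiguous pulses reproduce the sustained trajectory", {
  sys <- build_model("INTEGRATED", init = c(TIF1g_n = 5))
  y0 <- equilibrate(sys)
  tg <- seq(0, 2 * 3600, by = 300)
  sust <- simulate_system(sys, sustained10(), tg, y0 = y0)
  packed <- stimulus_protocol("pulse_train", concentration = 10,
                              pulse_width = 600, interval = 600)
  pls <- simulate_system(sys, packed, tg, y0 = y0)
  idx <- match(tg, sust$time); idx2 <- match(tg, pls$time)
  rel <- abs(sust$mat[idx, ] - pls$mat[idx2, ]) / pmax(abs(sust$mat[idx, ]), 1e-8)
  expect_lt(max(rel), 1e-6)
})

test_that("ligand_value clamps the input and tracks the depletable state", {
  s <- stimulus_protocol("sustained", concentration = 7)
  expect_identical(ligand_value(s, c(0, 10, 1e6)), c(7, 7, 7))
  w <- stimulus_protocol("window", concentration = 7, t_on = 100, t_off = 200)
  expect_identical(ligand_value(w, c(0, 150, 250)), c(0, 7, 0))
  p <- stimulus_protocol("pulse_train", concentration = 7, pulse_width = 60,
                         interval = 600, n_pulses = 2)
  expect_identical(ligand_value(p, c(30, 300, 630, 1230)), c(7, 0, 7, 0))
  d <- stimulus_protocol("sustained", concentration = 7, depletion = TRUE)
  expect_identical(ligand_value(d, 5, state = c(TGFb = 3.2)), 3.2)
  expect_error(ligand_value(d, 5, state = c(RI = 1)), "no depletable ligand")
  expect_error(stimulus_protocol("pulse_train", pulse_width = 900, interval = 300),
               "disjoint")
  expect_error(stimulus_protocol("window", t_on = 10, t_off = 5), "t_off")
})

test_that("depleted ligand is consumed monotonically and the large-bolus limit is the clamp", {
  vdep <- model_variant("INTEGRATED", ligand_depletion = TRUE)
  sys <- build_model(vdep, init = c(TIF1g_n = 10))
  tg <- short_grid(3)
  run_dep <- function(conc) {
    pr <- stimulus_protocol("sustained", concentration = conc, depletion = TRUE)
    simulate_system(sys, pr, tg)
  }
  tr5 <- run_dep(5)
  lig <- tr5$mat[, "TGFb"]
  expect_true(all(diff(lig) <= 1e-9))
  # mismatched protocol/model combinations are rejected both ways
  expect_error(simulate_system(sys, sustained10(), tg), "depleting protocol")
  expect_error(simulate_system(build_model("INTEGRATED"),
                               stimulus_protocol("sustained", depletion = TRUE),
                               tg), "no depletable ligand")
  # more ligand, closer to the non-depleting response
  clamp <- function(conc) {
    s2 <- build_model("INTEGRATED", init = c(TIF1g_n = 10))
    max(readout(simulate_system(s2, stimulus_protocol("sustained",
                                                      concentration = conc),
                                tg), "pS24n"))
  }
  gap <- function(conc) abs(max(readout(run_dep(conc), "pS24n")) - clamp(conc)) /
    clamp(conc)
  expect_lt(gap(100), gap(5))
})

test_that("the adaptive solution matches a fixed-small-step explicit integrator", {
  sys <- build_model("INTEGRATED", init = c(TIF1g_n = 0))
  y0 <- equilibrate(sys)
  tg <- seq(0, 1800, by = 300)
  traj <- simulate_system(sys, sustained10(), tg, y0 = y0)
  # classical RK4 with a step far below the fastest timescale
  f <- function(y) unname(model_rhs(sys, y, 0, ligand = 10))
  h <- 0.25
  y <- unname(y0); t <- 0
  out <- matrix(NA_real_, length(tg), length(y)); out[1, ] <- y
  for (i in 2:length(tg)) {
    while (t < tg[i] - 1e-9) {
      k1 <- f(y); k2 <- f(pmax(y + h / 2 * k1, 0))
      k3 <- f(pmax(y + h / 2 * k2, 0)); k4 <- f(pmax(y + h * k3, 0))
      y <- pmax(y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0); t <- t + h
    }
    out[i, ] <- y
  }
  idx <- match(tg, traj$time)
  rel <- abs(out - traj$mat[idx, ]) / pmax(abs(out), 1e-6)
  expect_lt(max(rel), 1e-6)
})
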