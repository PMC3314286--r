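test_that("the predicted relative curve is self-normalized and monotone", {
  ratios <- c(0, 0.25, 0.5, 1, 2)
  curve <- predict_relative_signal(ratios, t_grid = short_grid(3))
  expect_identical(curve$relative[curve$ratio == 0], 1)
  expect_true(all(diff(curve$relative) <= 1e-9))
  expect_true(all(curve$relative >= 0 & curve$relative <= 1))
})

test_that("the relative curve is the TIF1g scan rescaled", {
  tg <- short_grid(3)
  curve <- predict_relative_signal(c(0, 0.2, 0.5), t_grid = tg)
  sc <- scan_tif1g("INTEGRATED", tif1g_grid = c(0, 10, 25), t_grid = tg,
                   keep_curves = FALSE)
  expect_equal(curve$relative,
               sc$summary$peak_pS24n / sc$summary$peak_pS24n[1],
               tolerance = 1e-8)
})

test_that("noise-free affine data are recovered exactly", {
  curve <- toy_curve()
  cfg <- synth_config(ratios = curve$ratio, a = 3, b = 1, sd = 0, n = 2)
  data <- generate_ratio_dataset(cfg, curve)
  fit <- fit_scaling(data, curve)
  expect_equal(fit$a, 3, tolerance = 1e-10)
  expect_equal(fit$b, 1, tolerance = 1e-10)
  expect_lt(fit$rss, 1e-18)
})

test_that("degenerate fits behave predictably", {
  curve <- toy_curve()
  # constant fold changes: all signal goes into the offset
  data <- data.frame(ratio = curve$ratio, fold_change = 2.5)
  fit <- fit_scaling(data, curve)
  expect_equal(fit$a, 0, tolerance = 1e-10)
  expect_equal(fit$b, 2.5, tolerance = 1e-10)
  # a constant curve cannot identify the scale
  flat <- data.frame(ratio = curve$ratio, relative = 1)
  data2 <- data.frame(ratio = curve$ratio, fold_change = curve$ratio + 1)
  expect_error(fit_scaling(data2, flat), "rank deficiency")
  # fewer than 3 distinct ratios is refused
  expect_error(fit_scaling(data.frame(ratio = c(0, 0, 1),
                                      fold_change = c(1, 1, 2)), curve),
               "3 distinct")
  expect_error(fit_scaling(transform(data, sd = 0), curve, weighted = TRUE),
               "positive sd")
})

test_that("residuals are invariant to row order and weights are honored", {
  curve <- toy_curve()
  cfg <- synth_config(ratios = curve$ratio, a = 2, b = 1, sd = 0.2, n = 4,
                      seed = 11)
  data <- generate_ratio_dataset(cfg, curve)
  f1 <- fit_scaling(data, curve)
  perm <- sample(nrow(data))
  f2 <- fit_scaling(data[perm, ], curve)
  expect_equal(f2$a, f1$a, tolerance = 1e-12)
  expect_equal(sort(f2$residuals), sort(f1$residuals), tolerance = 1e-12)
  fw <- fit_scaling(data, curve, weighted = TRUE)
  expect_false(identical(fw$a, f1$a))
})

test_that("scale-only fits force the offset through zero", {
  curve <- toy_curve()
  data <- data.frame(ratio = curve$ratio,
                     fold_change = 4 * curve$relative)
  fit <- fit_scaling(data, curve, form = "scale")
  expect_equal(fit$a, 4, tolerance = 1e-10)
  expect_identical(fit$b, 0)
})

test_that("estimator bias vanishes with noise and replication", {
  curve <- toy_curve()
  mean_a <- function(sd, n, reps = 60) {
    mean(vapply(seq_len(reps), function(i) {
      d <- generate_ratio_dataset(
        synth_config(ratios = curve$ratio, a = 3, b = 1, sd = sd, n = n,
                     seed = 1000 + i), curve)
      fit_scaling(d, curve)$a
    }, numeric(1)))
  }
  expect_equal(mean_a(0, 10, reps = 3), 3, tolerance = 1e-10)
  bias05 <- abs(mean_a(0.05, 10) - 3) / 3
  bias10_big_n <- abs(mean_a(0.10, 100) - 3) / 3
  expect_lt(bias05, 0.05)
  expect_lt(bias10_big_n, 0.05)
})
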