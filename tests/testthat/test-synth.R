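test_that("generation is bit-identical under a fixed seed", {
  curve <- toy_curve()
  cfg <- synth_config(sd = 0.15, n = 5, seed = 99, ratios = curve$ratio)
  d1 <- generate_ratio_dataset(cfg, curve)
  d2 <- generate_ratio_dataset(cfg, curve)
  expect_identical(d1$fold_change, d2$fold_change)
  # and the generator does not disturb the caller's RNG stream
  set.seed(5); before <- runif(1)
  set.seed(5); invisible(generate_ratio_dataset(cfg, curve)); after <- runif(1)
  expect_identical(before, after)
})

test_that("zero noise lands exactly on the affine-transformed curve", {
  curve <- toy_curve()
  cfg <- synth_config(ratios = curve$ratio, a = 2.5, b = 1, sd = 0, n = 3)
  d <- generate_ratio_dataset(cfg, curve)
  expect_equal(d$fold_change,
               rep(2.5 * curve$relative + 1, each = 3), tolerance = 1e-12)
  expect_true(all(d$sd == 0))
})

test_that("generated datasets satisfy the ratio-dataset invariants", {
  curve <- toy_curve()
  for (noise in c("multiplicative_lognormal", "additive_gaussian")) {
    d <- generate_ratio_dataset(
      synth_config(ratios = curve$ratio, noise = noise, sd = 0.3, n = 4,
                   seed = 3), curve)
    expect_true(all(d$ratio >= 0))
    expect_true(all(d$fold_change >= 0))
    expect_true(all(d$sd >= 0))
    expect_gte(length(unique(d$ratio)), 3)
  }
  expect_error(synth_config(noise = "bogus"))
  expect_error(synth_config(sd = -1), "sd")
  expect_error(synth_config(n = 0), "replicate")
})

test_that("large-replicate means converge to the affine-transformed curve", {
  curve <- toy_curve()
  cfg <- synth_config(ratios = curve$ratio, a = 3, b = 1, sd = 0.1, n = 1e4,
                      seed = 7)
  d <- generate_ratio_dataset(cfg, curve)
  mu <- 3 * curve$relative + 1
  for (i in seq_along(curve$ratio)) {
    sub <- d$fold_change[d$ratio == curve$ratio[i]]
    se <- stats::sd(sub) / sqrt(length(sub))
    # lognormal noise at sdlog 0.1 inflates the mean by ~0.5%; allow for it
    expect_lt(abs(mean(sub) - mu[i]), 3 * se + 0.005 * mu[i])
  }
})

test_that("knockdown recovery follows the single-exponential return to basal", {
  kd <- generate_knockdown_timecourse("TIF1g", nadir_fraction = 0.05,
                                      recovery_rate = 0.5, days = 0:14)
  expect_equal(kd$level[1], 0.05, tolerance = 1e-12)
  expect_equal(kd$level[kd$day == 14], 1, tolerance = 1e-3)
  expect_true(all(diff(kd$level) > 0))
  # silencing TIF1g makes the TIF1g/Smad4 ratio climb back toward 1
  expect_true(all(diff(kd$ratio) > 0))
  expect_equal(kd$ratio, kd$level / kd$partner_level, tolerance = 1e-12)
  # closed form at day 2
  expect_equal(kd$level[kd$day == 2], 1 - 0.95 * exp(-1), tolerance = 1e-12)

  kd4 <- generate_knockdown_timecourse("Smad4", nadir_fraction = 0,
                                       recovery_rate = 1, days = 0:5)
  expect_identical(kd4$level[1], 0)
  expect_true(all(diff(kd4$ratio) < 0)) # Smad4 recovery lowers the ratio
  expect_error(generate_knockdown_timecourse("Smad4", nadir_fraction = 1),
               "nadir")
  expect_error(generate_knockdown_timecourse("Smad4", recovery_rate = 0),
               "recovery_rate")
})
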