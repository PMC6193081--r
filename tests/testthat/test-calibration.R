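test_that("clinical series validate their invariants", {
  expect_error(clinical_series("placebo", "AP", c(0, 1), c(50), c(1, 1)),
               "equal length")
  expect_error(clinical_series("placebo", "AP", c(1, 0), c(50, 50),
                               c(1, 1)), "increasing")
  expect_error(clinical_series("placebo", "AP", c(0, 1), c(50, -2),
                               c(1, 1)), ">= 0")
  expect_error(clinical_series("placebo", "AP", c(0, 1), c(50, 50),
                               c(1, 0)), "> 0")
  expect_error(clinical_series("placebo", "CRP", 0, 1, 1))
})

test_that("loss is zero at the generating truth and quadratic in offsets", {
  p <- nominal_params()
  series <- noiseless_series()
  bs <- series[grep("^bIAP_", names(series))]
  base <- series_loss(p, bs, appired2_protocol())
  expect_lt(base, 1e-4)

  # adding k*mae to every point raises the loss by ~ n*k^2
  k <- 1.7
  shifted <- lapply(bs, function(s) {
    clinical_series(s$branch, s$observable, s$time_h,
                    s$median + k * s$mae, s$mae)
  })
  n <- sum(vapply(bs, function(s) length(s$time_h), numeric(1)))
  expect_equal(series_loss(p, shifted, appired2_protocol()),
               n * k^2, tolerance = 0.01)
  expect_error(series_loss(p, list(), appired2_protocol()), "empty")
})

test_that("hand-computed loss on a 3-point series matches", {
  # homeostatic model: blood AP constant at its 50 IU/L baseline
  p <- model_parameters(itm_insult = 0)
  s <- clinical_series("placebo", "AP", c(1, 5, 20), c(49, 51, 50),
                       c(1, 2, 5))
  # ((50-49)/1)^2 + ((50-51)/2)^2 + 0 = 1.25
  expect_equal(series_loss(p, list(s), placebo_protocol()), 1.25,
               tolerance = 1e-4)
})

test_that("a single free parameter is recovered from noiseless data", {
  cfg <- synth_config(noise_fraction = 0)
  rec <- parameter_recovery_suite(cfg, "r_induce_peak", n_seeds = 1,
                                  n_global = 50, n_local = 80)
  expect_equal(nrow(rec), 1)
  expect_lt(rec$rel_error, 0.01)
})

test_that("fitting is seed-deterministic and never worse than its start", {
  p <- nominal_params()
  series <- noisy_series()
  bs <- series[grep("^bIAP_", names(series))]
  f1 <- fit_parameters(p, bs, appired2_protocol(), free = "r_induce_peak",
                       seed = 3, n_global = 12, n_local = 10)
  f2 <- fit_parameters(p, bs, appired2_protocol(), free = "r_induce_peak",
                       seed = 3, n_global = 12, n_local = 10)
  expect_identical(f1$params$values, f2$params$values)
  expect_identical(f1$loss, f2$loss)
  start_loss <- series_loss(p, bs, appired2_protocol())
  expect_lte(f1$loss, start_loss)
  # the reported loss is reproducible from the fitted parameters
  expect_equal(series_loss(f1$params, bs, appired2_protocol()), f1$loss,
               tolerance = 1e-10)
})

test_that("collapsed bounds return that point with its loss", {
  p <- nominal_params()
  pin <- 0.42
  p$lower[["r_induce_peak"]] <- pin
  p$upper[["r_induce_peak"]] <- pin
  p <- set_parameter_values(p, c(r_induce_peak = pin))
  series <- noiseless_series()
  bs <- series[grep("^bIAP_", names(series))]
  f <- fit_parameters(p, bs, appired2_protocol(), free = "r_induce_peak",
                      seed = 1, n_global = 10, n_local = 10)
  expect_equal(f$params$values[["r_induce_peak"]], pin)
  expect_equal(f$loss, series_loss(f$params, bs, appired2_protocol()),
               tolerance = 1e-10)
})

test_that("cross-validation: identity on the fitted branch, degradation away
           from truth, mismatched observables rejected", {
  p <- nominal_params()
  series <- noisy_series()
  bs <- series[grep("^bIAP_", names(series))]
  ps <- series[grep("^placebo_", names(series))]
  f <- fit_parameters(p, bs, appired2_protocol(), free = "r_induce_peak",
                      seed = 2, n_global = 10, n_local = 10)
  # validating on the fitted branch reproduces the fit residuals
  self_res <- cross_validate(f, bs, appired2_protocol())
  expect_equal(self_res, f$residuals, tolerance = 1e-9)

  # noise-only validation: placebo residuals at the truth are comparable
  # to calibration residuals (same noise model), far from pathological
  val <- cross_validate(p, ps, placebo_protocol())
  calib <- cross_validate(p, bs, appired2_protocol())
  expect_lt(sum(val), 20 * sum(calib) + 20)

  # gross parameter distortion degrades validation residuals
  bad <- set_parameter_values(p, c(k_aps_deg_blood = 100,
                                   r_induce_peak = 6))
  expect_gt(sum(cross_validate(bad, bs, appired2_protocol())), sum(calib))

  broken <- ps
  broken[[1]]$observable <- "CRP"
  expect_error(cross_validate(p, broken, placebo_protocol()),
               "observable")
})
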