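test_that("progress_curve validates its inputs", {
  expect_error(progress_curve(c(0, 1, 1), c(1, 2, 3)), "increasing")
  expect_error(progress_curve(0:2, c(1, NA, 3)), "finite")
  expect_error(progress_curve(0:2, 1:2), "same length")
  cv <- progress_curve(0:4, (0:4) * 2, kind = "absorbance")
  expect_s3_class(cv, "progress_curve")
  df <- as.data.frame(cv)
  expect_named(df, c("time_s", "value", "kind"))
})

test_that("detect_lag: a linear curve through the origin has zero lag", {
  t <- seq(0, 100, by = 1)
  res <- detect_lag(progress_curve(t, 0.25 * t))
  expect_equal(res$lag_time, 0, tolerance = 1e-8)
  expect_equal(res$steady_rate, 0.25, tolerance = 1e-10)
  expect_gte(res$r_squared, 0.999999)
})

test_that("detect_lag: integrated burst model has lag -> 1/k", {
  k <- 0.02; V <- 0.7
  t <- seq(0, 600, by = 0.5)
  curve <- progress_curve(t, V * (t - (1 - exp(-k * t)) / k))
  res <- detect_lag(curve, window_frac = 0.05)
  expect_equal(res$lag_time, 1 / k, tolerance = 0.02)
  expect_equal(res$steady_rate, V, tolerance = 0.01)
})

test_that("detect_lag invariances: time shift, value scaling", {
  k <- 0.02; V <- 0.7
  t <- seq(0, 600, by = 0.5)
  y <- V * (t - (1 - exp(-k * t)) / k)
  base <- detect_lag(progress_curve(t, y))
  shifted <- detect_lag(progress_curve(t + 1000, y))
  expect_equal(shifted$lag_time, base$lag_time, tolerance = 1e-6)
  scaled <- detect_lag(progress_curve(t, 50 * y))
  expect_equal(scaled$lag_time, base$lag_time, tolerance = 1e-8)
  expect_equal(scaled$steady_rate, 50 * base$steady_rate, tolerance = 1e-8)
})

test_that("detect_lag rejects bad inputs", {
  t <- seq(0, 20, 1)
  expect_error(detect_lag(progress_curve(t, 20 - t)), "decreasing")
  expect_error(detect_lag(progress_curve(0:5, 0:5 * 1.0)), ">= 10 points")
  expect_error(detect_lag(progress_curve(t, t * 1.0), window_frac = 0), "window_frac")
})

test_that("kobs_from_p31 unit arithmetic and edge cases", {
  t <- seq(0, 2000, by = 10)
  frac <- progress_curve(t, 1.1e-4 * t, kind = "normalised_integral")
  res <- kobs_from_p31(frac, substrate_total = 1e4, E_T = 1)
  expect_equal(res$k_obs, 1.1, tolerance = 1e-9)
  flat <- progress_curve(t, rep(0.2, length(t)), kind = "normalised_integral")
  expect_equal(kobs_from_p31(flat, 1e4, 1)$k_obs, 0)
  expect_error(kobs_from_p31(progress_curve(t, t * 1e-4), 1e4, 1),
               "normalised_integral")
  expect_error(kobs_from_p31(frac, 1e4, 0), "positive")
  # exact linearity in 1/E_T
  expect_equal(kobs_from_p31(frac, 1e4, 0.5)$k_obs,
               2 * kobs_from_p31(frac, 1e4, 1)$k_obs)
})

test_that("kobs_from_p31 finds the linear segment of a lag/linear/plateau curve", {
  t <- seq(0, 6000, by = 20)
  # smooth lag (time constant 400 s) into a 2e-4/s linear phase, capped
  ramp <- 2e-4 * (t - 400 * (1 - exp(-t / 400)))
  y <- pmin(ramp, 0.6)
  curve <- progress_curve(t, y, kind = "normalised_integral")
  # default 0.999 threshold tolerates part of the curved onset; a tighter
  # threshold confines the window to the truly linear phase
  res <- kobs_from_p31(curve, substrate_total = 1e4, E_T = 2, r2_min = 0.9999)
  expect_equal(res$k_obs, 2e-4 * 1e4 / 2, tolerance = 0.02)
  expect_gt(res$window[1L], 400)         # skips the curved onset
  # manual segment selection agrees
  man <- kobs_from_p31(curve, 1e4, 2, segment = c(1600, 3000))
  expect_equal(man$k_obs, res$k_obs, tolerance = 0.02)
  # a hopeless curve errors with advice to pick bounds manually
  wig <- progress_curve(t, sin(t / 50) * 0.2 + 0.5, kind = "normalised_integral")
  expect_error(kobs_from_p31(wig, 1e4, 2, r2_min = 0.999999), "manual")
})

test_that("apparent_dephos_rate recovers -slope/E_T", {
  t <- seq(0, 2000, by = 10)
  dep <- progress_curve(t, 50000 - 0.6 * t)
  res <- apparent_dephos_rate(dep, E_T = 200)
  expect_equal(res$rate, 0.003, tolerance = 1e-9)
  # exact linearity in 1/E_T
  expect_equal(apparent_dephos_rate(dep, E_T = 100)$rate, 0.006,
               tolerance = 1e-9)
  expect_error(apparent_dephos_rate(progress_curve(t, rep(5, length(t)))),
               "no depletion")
  expect_error(apparent_dephos_rate(progress_curve(t, 5 + 0.001 * t)),
               "nondecreasing|decreasing")
})

test_that("dephos round trip through the simulator recovers the constant", {
  sc <- dephos_assay_scheme()
  tr <- integrate_scheme(sc, c(B = 200, agent = 50000), seq(0, 1500, by = 5))
  curve <- progress_curve(tr$times, tr$conc[, "agent"])
  res <- apparent_dephos_rate(curve, E_T = 200)
  expect_equal(res$rate, 0.003, tolerance = 0.01)
})

test_that("absorbance/concentration conversion is the exact inverse", {
  a <- progress_curve(0:3, c(0, 0.1, 0.3, 0.622), kind = "absorbance")
  conc <- absorbance_to_concentration(a)
  expect_equal(conc$values[4L], 100)
  expect_equal(conc$values[1L], 0)
  expect_equal(conc$kind, "concentration")
  expect_error(absorbance_to_concentration(conc), "absorbance")
  expect_error(absorbance_to_concentration(a, epsilon = 0), "positive")
  # composition with the forward observable is the identity
  tr <- structure(list(times = 0:3, conc = cbind(NADH = c(0, 20, 50, 90)),
                       scheme_hash = 0, solver = list()), class = "trajectory")
  back <- absorbance_to_concentration(absorbance_observable(tr))
  expect_equal(back$values, c(0, 20, 50, 90), tolerance = 1e-12)
})

test_that("generator->analyser round trips recover rates across noise seeds", {
  t <- seq(0, 2000, by = 10)
  true_rate <- 0.003
  errs <- vapply(1:50, function(s) {
    y <- with_seed(s, (50000 - true_rate * 200 * t) *
                      (1 + rnorm(length(t), 0, 0.0005)))
    res <- apparent_dephos_rate(progress_curve(t, y), E_T = 200, r2_min = 0.99)
    abs(res$rate - true_rate) / true_rate
  }, 0)
  expect_lt(median(errs), 0.02)
})
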