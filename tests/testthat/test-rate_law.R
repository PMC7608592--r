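test_that("evaluate_rate handles boundary substrate concentrations", {
  p <- wt_truth
  expect_equal(evaluate_rate(p, 0, 10, 0.001), 0)
  expect_equal(evaluate_rate(p, 100, 0, 0.001), 0)
  expect_error(evaluate_rate(p, 0, 0, 0.001), "both substrate")
  expect_error(evaluate_rate(p, -1, 10, 0.001), ">= 0")
  expect_error(evaluate_rate(p, 100, 10, 0), "positive")
  bad <- unclass(p); bad$k_cat <- -1
  expect_error(evaluate_rate(bad, 100, 10, 0.001), "positive")
})

test_that("evaluate_rate saturates to k_cat*E_T without inhibition", {
  p <- kinetic_params(382, 91, 8.5, Inf)
  S <- 1e9 * 91
  v <- evaluate_rate(p, S, S, 0.001)
  expect_equal(v / (382 * 0.001), 1, tolerance = 1e-6)
})

test_that("evaluate_rate agrees with a term-by-term oracle to 1e-12 relative", {
  # frozen hand-derived value for the wild-type constants
  expect_equal(evaluate_rate(wt_truth, 100, 10, 0.001), 0.13563937,
               tolerance = 1e-7)
  set.seed(42)
  for (i in 1:200) {
    k_cat <- 10^runif(1, -1, 3); K_S <- 10^runif(1, 0, 3)
    K_I <- 10^runif(1, -1, 3)
    K_i <- if (i %% 4 == 0) Inf else 10^runif(1, 1, 4)
    S <- 10^runif(1, -2, 4); I <- 10^runif(1, -2, 4); E_T <- 10^runif(1, -3, 1)
    p <- kinetic_params(k_cat, K_S, K_I, K_i)
    expect_equal(evaluate_rate(p, S, I, E_T),
                 rate_law_oracle(k_cat, K_S, K_I, K_i, S, I, E_T),
                 tolerance = 1e-12)
  }
})

test_that("rate is exactly linear in enzyme concentration", {
  v1 <- evaluate_rate(wt_truth, 137, 3.3, 0.004)
  v2 <- evaluate_rate(wt_truth, 137, 3.3, 0.008)
  expect_identical(v2, 2 * v1)
})

test_that("substrate-inhibition shape: interior maximum iff K_i finite", {
  S <- exp(seq(log(0.1), log(1e6), length.out = 400))
  v_inh <- evaluate_rate(wt_truth, S, 10, 0.001)
  sign_changes <- sum(diff(sign(diff(v_inh))) != 0)
  expect_equal(sign_changes, 1)              # one interior maximum
  expect_gt(which.max(v_inh), 1)
  expect_lt(which.max(v_inh), length(S))
  p_no <- kinetic_params(382, 91, 8.5, Inf)
  v_mono <- evaluate_rate(p_no, S, 10, 0.001)
  expect_true(all(diff(v_mono) >= 0))
})

test_that("global fit recovers generating parameters from a noiseless grid", {
  tab <- noiseless_table("WT")
  fit <- global_fit(tab, start = perturbed_start(wt_truth))
  expect_true(fit$converged)
  v <- as.numeric(fit$params)
  truth <- as.numeric(wt_truth)
  for (nm in names(truth)) expect_lt(rel_err(v[[nm]], truth[[nm]]), 1e-3)
  expect_equal(fit$n_used, 55)
  expect_equal(fit$n_excluded, 0)
})

test_that("noiseless recovery succeeds from any start within x/÷10 of truth", {
  tab <- noiseless_table("P146A")
  set.seed(7)
  for (i in 1:5) {
    fac <- 10^runif(4, -1, 1)
    start <- kinetic_params(p146a_truth$k_cat * fac[1],
                            p146a_truth$K_bG1P * fac[2],
                            p146a_truth$K_bG16BP * fac[3],
                            p146a_truth$K_i * fac[4])
    fit <- global_fit(tab, start = start)
    v <- as.numeric(fit$params); truth <- as.numeric(p146a_truth)
    for (nm in names(truth)) expect_lt(rel_err(v[[nm]], truth[[nm]]), 1e-3)
  }
})

test_that("plain ping-pong data fitted without inhibition has ~zero residual", {
  p0 <- kinetic_params(50, 40, 20, Inf)
  g <- bpgm_grid("WT")
  tab <- gen_rate_table(p0, g$bG1P, g$bG16BP, 0.01, replicates = 1L,
                        noise = noise_model(0))
  fit <- global_fit(tab, start = kinetic_params(100, 100, 100, Inf))
  expect_lt(fit$residual_norm, 1e-12)
  expect_false(is.finite(fit$params$K_i))
})

test_that("filtering and replicate handling are reported", {
  g <- bpgm_grid("P146A")
  tab <- gen_rate_table(p146a_truth, g$bG1P, g$bG16BP, g$E_T,
                        replicates = 3L, noise = noise_model(0))
  fit <- global_fit(tab, start = perturbed_start(p146a_truth),
                    filter_max_bG16BP = 10)
  expect_equal(fit$n_excluded, 11 * 3 * 3)   # three high-bG16BP levels, triplicate
  expect_equal(fit$n_used, 11 * 3)           # replicate means
  # filtered noiseless data still identify the true parameters
  expect_lt(rel_err(fit$params$k_cat, p146a_truth$k_cat), 1e-3)
})

test_that("underdetermined designs raise errors", {
  tab <- data.frame(bG1P_uM = c(10, 20, 30), bG16BP_uM = 5, ET_uM = 0.001,
                    v0_uM_per_s = c(0.01, 0.02, 0.03), replicate = 1L)
  expect_error(global_fit(tab), "underdetermined")
})

test_that("bootstrap standard deviations are finite and nonnegative", {
  g <- bpgm_grid("WT")
  tab <- gen_rate_table(wt_truth, g$bG1P, g$bG16BP, g$E_T, replicates = 3L,
                        noise = noise_model(0.02, seed = 11L))
  fit <- global_fit(tab, start = perturbed_start(wt_truth),
                    sd_method = "bootstrap", n_boot = 25L, boot_seed = 5L)
  expect_true(all(is.finite(fit$param_sd)))
  expect_true(all(fit$param_sd >= 0))
})

test_that("fit_initial_rate returns the least-squares slope on a window", {
  t <- seq(0, 100, by = 1)
  lin <- progress_curve(t, 0.5 * t + 2)
  expect_equal(fit_initial_rate(lin)$slope, 0.5, tolerance = 1e-12)
  flat <- progress_curve(t, rep(3, length(t)))
  expect_equal(fit_initial_rate(flat)$slope, 0)
  expect_error(fit_initial_rate(lin, window = c(-10, 5)), "outside")
  expect_error(fit_initial_rate(lin, window = c(0, 1.5)), ">= 3 points")
  # integrated burst model: P'(0) = 0, so the near-origin slope shrinks
  # with the window (Taylor oracle)
  k <- 0.05; V <- 1
  tt <- seq(0, 400, by = 0.5)
  burst <- progress_curve(tt, V * (tt - (1 - exp(-k * tt)) / k))
  s_wide <- fit_initial_rate(burst, window = c(0, 40))$slope
  s_narrow <- fit_initial_rate(burst, window = c(0, 4))$slope
  expect_lt(s_narrow, s_wide)
  expect_lt(s_narrow, V * k * 4)  # bounded by P''(0) * window
})
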