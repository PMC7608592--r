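test_that("scheme construction encodes the pathway topology", {
  sc_g16 <- build_allomorphy_scheme("bG16BP")
  makes_BP <- vapply(sc_g16$reactions,
                     function(r) "B_P" %in% names(r$products), TRUE)
  expect_false(any(makes_BP))  # intermediate-driven pathway never makes B_P
  expect_false("agent" %in% sc_g16$species)

  sc_f <- build_allomorphy_scheme("F16BP")
  expect_equal(sc_f$byproduct_name, "fructose monophosphate")
  expect_equal(sc_f$composition["phosphate", "agent"], 2)
  sc_a <- build_allomorphy_scheme("AcP")
  expect_equal(sc_a$byproduct_name, "acetate")
  expect_equal(sc_a$composition["phosphate", "agent"], 1)

  expect_error(build_allomorphy_scheme("G6P"), "arg")
  expect_error(build_allomorphy_scheme("F16BP", overrides = list(k_nope = 1)),
               "unknown rate override")
  expect_error(build_allomorphy_scheme("F16BP", overrides = list(k_AB = -1)),
               "nonnegative")
})

two_state_scheme <- function(k_AB, k_BA) {
  build_allomorphy_scheme("F16BP", overrides = list(
    k_AB = k_AB, k_BA = k_BA, k_phos_A = 0, k_phos_B = 0,
    k_hyd_AP = 0, k_hyd_BP = 0, k_act_G16BP = 0, f_release = 0))
}

test_that("pure A<->B system matches the analytic two-state relaxation", {
  sc <- two_state_scheme(0.5, 0.5)
  tg <- seq(0, 20, by = 0.25)
  tr <- integrate_scheme(sc, c(A = 1), tg)
  analytic <- 0.5 + 0.5 * exp(-1.0 * tg)  # rate k_AB + k_BA
  expect_lt(max(abs(tr$conc[, "A"] - analytic)), 1e-6)
  expect_lt(max(abs(tr$conc[, "B"] - (1 - analytic))), 1e-6)
})

test_that("the 70:30 equilibrium start is a fixed point", {
  sc <- two_state_scheme(0.03, 0.07)
  tr <- integrate_scheme(sc, c(A = 0.7, B = 0.3), seq(0, 100, by = 10))
  expect_lt(max(abs(tr$conc[, "A"] - 0.7)), 1e-9)
  expect_lt(max(abs(tr$conc[, "B"] - 0.3)), 1e-9)
})

test_that("integration conserves enzyme and moiety totals to 1e-8 relative", {
  for (ag in c("F16BP", "AcP", "bG16BP")) {
    sc <- build_allomorphy_scheme(ag)
    init <- c(A = 0.7 * 0.02, B = 0.3 * 0.02, bG1P = 50)
    if (ag == "bG16BP") init["bG16BP"] <- 10 else init["agent"] <- 1000
    tr <- integrate_scheme(sc, init, seq(0, 300, by = 10))
    drift <- conservation_drift(tr, sc)
    expect_lt(max(drift), 1e-8)
  }
})

test_that("no B_P accumulates on the bG16BP-initiated pathway", {
  sc <- build_allomorphy_scheme("bG16BP")
  E_T <- 0.02
  tr <- integrate_scheme(sc, c(A = 0.7 * E_T, B = 0.3 * E_T,
                               bG1P = 50, bG16BP = 10),
                         seq(0, 200, by = 5))
  expect_lt(max(tr$conc[, "B_P"]), 1e-3 * E_T)
})

test_that("integration is deterministic and validates its inputs", {
  sc <- build_allomorphy_scheme("AcP")
  init <- c(A = 0.01, bG1P = 50, agent = 8000)
  t1 <- integrate_scheme(sc, init, seq(0, 50, 5))
  t2 <- integrate_scheme(sc, init, seq(0, 50, 5))
  expect_identical(t1$conc, t2$conc)
  expect_error(integrate_scheme(sc, c(A = 0.01, nonspecies = 1), seq(0, 10, 1)),
               "unknown species")
  expect_error(integrate_scheme(sc, c(A = -1), seq(0, 10, 1)), "nonnegative")
  expect_error(integrate_scheme(sc, init, c(0, 2, 1)), "increasing")
  expect_error(integrate_scheme(sc, init, seq(0, 10, 1), rtol = 0), "positive")
})

test_that("with frozen phospho-enzyme the scheme reproduces the rate law", {
  # all enzyme in A_P, no hydrolysis/release: d[G6P]/dt must equal the
  # closed-form initial rate within 1%
  sc <- build_allomorphy_scheme("F16BP", overrides = list(
    k_phos_A = 0, k_phos_B = 0, k_hyd_AP = 0, k_hyd_BP = 0,
    k_act_G16BP = 0, f_release = 0))
  E_T <- 0.001
  tr <- integrate_scheme(sc, c(A_P = E_T, bG1P = 100, bG16BP = 10),
                         seq(0, 0.2, by = 0.01))
  dG6P <- diff(tr$conc[, "G6P"]) / diff(tr$times)
  expect_equal(dG6P[1L], evaluate_rate(wt_truth, 100, 10, E_T),
               tolerance = 0.01)
})

fake_trajectory <- function(times, conc) {
  structure(list(times = times, conc = conc, scheme_hash = 0,
                 solver = list()), class = "trajectory")
}

test_that("absorbance observable is Beer-Lambert on the NADH trace", {
  tr <- fake_trajectory(0:2, cbind(NADH = c(0, 50, 100),
                                   bG1P = c(100, 50, 0), G6P = c(0, 50, 100)))
  a <- absorbance_observable(tr)
  expect_equal(a$values, 6220 * 1e-6 * c(0, 50, 100))
  expect_equal(a$values[3L], 0.622)
  expect_equal(absorbance_observable(tr, path = 0.5)$values[3L], 0.311)
  zero <- fake_trajectory(0:5, cbind(NADH = numeric(6)))
  expect_true(all(absorbance_observable(zero)$values == 0))
  expect_error(absorbance_observable(fake_trajectory(0:1, cbind(G6P = c(0, 1)))),
               "NADH")
  expect_error(absorbance_observable(tr, epsilon_NADH = -1), "positive")
})

test_that("full conversion of 50 uM substrate plateaus near A340 = 0.311", {
  sc <- build_allomorphy_scheme("bG16BP")
  E_T <- 0.02
  tr <- integrate_scheme(sc, c(A = 0.7 * E_T, B = 0.3 * E_T,
                               bG1P = 50, bG16BP = 10),
                         seq(0, 600, by = 5))
  plateau <- max(absorbance_observable(tr)$values)
  # >= the 50 uM stoichiometric endpoint; a few uM extra can come from
  # converted intermediate
  expect_gt(plateau, 0.31)
  expect_lt(plateau, 0.311 * 1.25)
})

test_that("31P observables are correctly normalised and conserved", {
  # no enzyme: nothing moves
  sc <- build_allomorphy_scheme("AcP")
  tr0 <- integrate_scheme(sc, c(bG1P = 1000, agent = 2000), seq(0, 100, 10))
  obs0 <- p31_observable(tr0)
  expect_true(all(obs0$bG1P$values == 1))
  expect_true(all(obs0$G6P$values == 0))
  # with enzyme: fractions + intermediate account for all glucose
  tr <- integrate_scheme(sc, c(A = 1.4, B = 0.6, bG1P = 1000, agent = 2000),
                         seq(0, 400, by = 10))
  obs <- p31_observable(tr)
  total <- obs$bG1P$values + obs$G6P$values + tr$conc[, "bG16BP"] / 1000
  expect_true(all(total <= 1 + 1e-8))
  expect_equal(max(obs$bG1P$values + obs$G6P$values), 1, tolerance = 1e-3)
  expect_error(p31_observable(tr0[c("times", "conc")]), "trajectory")
  trz <- integrate_scheme(sc, c(A = 1, agent = 10), seq(0, 10, 1))
  expect_error(p31_observable(trz), "zero initial phosphosugar")
})
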