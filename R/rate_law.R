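# Ping-pong bi-bi rate law with betaG1P substrate inhibition, and its global
# fit to initial-rate grids.

#' Kinetic parameter set for the betaPGM mutase reaction
#'
#' Bundles the four constants of the ping-pong bi-bi rate law with betaG1P
#' substrate inhibition: the turnover number `k_cat` (1/s), the Michaelis
#' constants for betaG1P and betaG16BP (uM), and the betaG1P inhibition
#' constant `K_i` (uM). `K_i = Inf` disables inhibition, reducing the law to
#' the plain ping-pong form.
#'
#' @param k_cat turnover number (1/s), > 0.
#' @param K_bG1P Michaelis constant for betaG1P (uM), > 0.
#' @param K_bG16BP Michaelis constant for betaG16BP (uM), > 0.
#' @param K_i betaG1P substrate-inhibition constant (uM), > 0; may be `Inf`.
#' @return an object of class `kinetic_params`.
#' @examples
#' kinetic_params(382, 91, 8.5, 1510)
#' @export
kinetic_params <- function(k_cat, K_bG1P, K_bG16BP, K_i = Inf) {
  p <- list(k_cat = k_cat, K_bG1P = K_bG1P, K_bG16BP = K_bG16BP, K_i = K_i)
  validate_kinetic_params(p)
  structure(p, class = "kinetic_params")
}

validate_kinetic_params <- function(p) {
  for (nm in c("k_cat", "K_bG1P", "K_bG16BP", "K_i")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop("kinetic parameter '", nm, "' must be a single positive number")
  }
  if (!is.finite(p$k_cat) || !is.finite(p$K_bG1P) || !is.finite(p$K_bG16BP))
    stop("k_cat and Michaelis constants must be finite")
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "Kinetic parameters: k_cat = %.4g /s, Km(bG1P) = %.4g uM, Km(bG16BP) = %.4g uM, Ki(bG1P) = %.4g uM\n",
    x$k_cat, x$K_bG1P, x$K_bG16BP, x$K_i))
  invisible(x)
}

#' @export
as.double.kinetic_params <- function(x, ...) {
  c(k_cat = x$k_cat, K_bG1P = x$K_bG1P, K_bG16BP = x$K_bG16BP, K_i = x$K_i)
}

#' Published betaPGM kinetic constants and assay concentration grids
#'
#' `bpgm_params()` returns the literature parameter sets for wild-type betaPGM
#' and the P146A variant (coupled-assay global fits at 298 K);
#' `bpgm_grid()` returns the corresponding betaG1P/betaG16BP concentration
#' lists and total enzyme concentration used on the assay plates. These serve
#' as generating truths for synthetic-data recovery experiments.
#'
#' @param variant `"WT"` or `"P146A"`.
#' @return `bpgm_params()`: a [kinetic_params()]; `bpgm_grid()`: a list with
#'   elements `bG1P` (uM), `bG16BP` (uM) and `E_T` (uM).
#' @examples
#' bpgm_params("WT")
#' bpgm_grid("P146A")$bG16BP
#' @export
bpgm_params <- function(variant = c("WT", "P146A")) {
  switch(match.arg(variant),
    WT    = kinetic_params(k_cat = 382,  K_bG1P = 91,  K_bG16BP = 8.5, K_i = 1510),
    P146A = kinetic_params(k_cat = 19.2, K_bG1P = 157, K_bG16BP = 175, K_i = 933))
}

#' @rdname bpgm_params
#' @export
bpgm_grid <- function(variant = c("WT", "P146A")) {
  switch(match.arg(variant),
    WT = list(
      bG1P   = c(10, 20, 30, 50, 70, 100, 150, 200, 300, 500, 700),
      bG16BP = c(0.4, 1, 2, 5, 10),
      E_T    = 0.001),
    P146A = list(
      bG1P   = c(5, 10, 15, 20, 30, 50, 70, 100, 200, 300, 500),
      bG16BP = c(2, 5, 10, 35, 50, 100),
      E_T    = 0.1))
}

#' Evaluate the ping-pong substrate-inhibition rate law
#'
#' Initial rate of the mutase reaction,
#' \deqn{v_0 = \frac{k_{cat} [E_T] S I}{S I + K_S I + K_I S (K_i + S)/K_i}}
#' with \eqn{S} = betaG1P, \eqn{I} = betaG16BP, \eqn{K_S} = Km(betaG1P),
#' \eqn{K_I} = Km(betaG16BP). The rate is 0 whenever either substrate is
#' absent (and the other present); both absent is undefined.
#'
#' @param params a [kinetic_params()].
#' @param bG1P betaG1P concentration(s), uM, >= 0.
#' @param bG16BP betaG16BP concentration(s), uM, >= 0.
#' @param E_T total enzyme concentration, uM, > 0.
#' @return initial rate(s), uM/s; vectorised over the concentration pair.
#' @examples
#' evaluate_rate(bpgm_params("WT"), bG1P = 100, bG16BP = 10, E_T = 0.001)
#' @export
evaluate_rate <- function(params, bG1P, bG16BP, E_T) {
  validate_kinetic_params(params)
  if (length(E_T) != 1L || !is.finite(E_T) || E_T <= 0)
    stop("E_T must be a single positive concentration (uM)")
  n <- max(length(bG1P), length(bG16BP))
  S <- rep_len(bG1P, n); I <- rep_len(bG16BP, n)
  if (any(S < 0) || any(I < 0)) stop("concentrations must be >= 0")
  if (any(S == 0 & I == 0))
    stop("rate undefined when both substrate concentrations are zero")
  inhib <- if (is.finite(params$K_i)) (params$K_i + S) / params$K_i else 1
  denom <- S * I + params$K_bG1P * I + params$K_bG16BP * S * inhib
  params$k_cat * E_T * S * I / denom
}

#' Globally fit the rate law to an initial-rate table
#'
#' Minimises the sum of squared deviations between observed initial rates and
#' [evaluate_rate()] over all (betaG1P, betaG16BP) conditions simultaneously,
#' for the four parameters (k_cat, Km(betaG1P), Km(betaG16BP), K_i) or three
#' when inhibition is disabled. Optimisation is in log-parameter space, which
#' enforces positivity without constraints. Parameter standard deviations come
#' from the Jacobian-based covariance scaled by the residual variance
#' (delta-method back-transform from log space); a seeded residual bootstrap
#' is available as an alternative.
#'
#' @param data a data frame with columns `bG1P_uM`, `bG16BP_uM`, `ET_uM`,
#'   `v0_uM_per_s` and optionally `replicate` (see [read_rate_table()]).
#' @param start starting [kinetic_params()]; `NULL` uses a scale-free
#'   heuristic (k_cat = max(v0)/E_T, Michaelis constants = medians of the
#'   concentration lists, K_i = 10 x max betaG1P). A start with `K_i = Inf`
#'   fits the plain ping-pong law (inhibition disabled).
#' @param filter_max_bG16BP drop rows with betaG16BP above this value (uM)
#'   before fitting, as done for the wild-type plate data where the model
#'   stops describing the high-betaG16BP points; `NULL` (default) keeps all.
#' @param average_replicates fit per-condition replicate means (default) or
#'   every point.
#' @param sd_method `"jacobian"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap resamples when `sd_method = "bootstrap"`.
#' @param boot_seed seed for the residual bootstrap.
#' @return an object of class `rate_fit`: list with `params`
#'   ([kinetic_params()]), `param_sd` (named, same units), `residual_norm`
#'   (sum of squared residuals, (uM/s)^2), `n_used`, `n_excluded` and
#'   `converged`. Non-convergence is flagged, not thrown.
#' @examples
#' tab <- gen_rate_table(bpgm_params("WT"), noise = noise_model(0))
#' global_fit(tab)
#' @export
global_fit <- function(data, start = NULL, filter_max_bG16BP = NULL,
                       average_replicates = TRUE,
                       sd_method = c("jacobian", "bootstrap"),
                       n_boot = 1000L, boot_seed = 1L) {
  sd_method <- match.arg(sd_method)
  check_rate_table(data)
  n_input <- nrow(data)
  if (!is.null(filter_max_bG16BP))
    data <- data[data$bG16BP_uM <= filter_max_bG16BP, , drop = FALSE]
  n_excluded <- n_input - nrow(data)
  if (average_replicates) {
    data <- stats::aggregate(
      v0_uM_per_s ~ bG1P_uM + bG16BP_uM + ET_uM, data = data, FUN = mean)
  }
  conds <- unique(data[, c("bG1P_uM", "bG16BP_uM")])
  if (nrow(conds) < 4L)
    stop("underdetermined fit: need >= 4 distinct (bG1P, bG16BP) conditions, have ",
         nrow(conds))
  if (is.null(start)) {
    start <- kinetic_params(
      k_cat    = max(data$v0_uM_per_s / data$ET_uM),
      K_bG1P   = stats::median(unique(data$bG1P_uM)),
      K_bG16BP = stats::median(unique(data$bG16BP_uM)),
      K_i      = 10 * max(data$bG1P_uM))
  }
  validate_kinetic_params(start)
  fit_Ki <- is.finite(start$K_i)
  par_names <- c("k_cat", "K_bG1P", "K_bG16BP", if (fit_Ki) "K_i")
  if (nrow(data) < length(par_names))
    stop("underdetermined fit: fewer points than parameters")

  to_params <- function(lp) {
    v <- exp(lp)
    kinetic_params(v[1L], v[2L], v[3L], if (fit_Ki) v[4L] else Inf)
  }
  resid_fn_for <- function(v0) {
    function(lp) {
      p <- to_params(lp)
      v0 - evaluate_rate(p, data$bG1P_uM, data$bG16BP_uM, E_T = 1) * data$ET_uM
    }
  }
  lp0 <- log(unlist(start[par_names], use.names = FALSE))
  # log-space step clamp (factor ~20 per iteration) keeps the weakly
  # determined K_i direction from overshooting to +infinity early on
  res <- lm_least_squares(lp0, resid_fn_for(data$v0_uM_per_s), max_step = 3)
  params <- to_params(res$par)

  p <- length(par_names)
  n <- nrow(data)
  if (sd_method == "jacobian") {
    cov_lp <- lm_covariance(res$jacobian, res$sse, n, p)
    sd_lp <- sqrt(pmax(diag(cov_lp), 0))
    param_sd <- sd_lp * exp(res$par)  # delta method: sd(exp(x)) ~ exp(x) sd(x)
  } else {
    fitted <- data$v0_uM_per_s - res$residuals
    param_sd <- with_seed(boot_seed, {
      draws <- vapply(seq_len(n_boot), function(b) {
        v0b <- fitted + sample(res$residuals, n, replace = TRUE)
        exp(lm_least_squares(res$par, resid_fn_for(v0b), maxit = 100L)$par)
      }, numeric(p))
      apply(draws, 1L, stats::sd)
    })
  }
  names(param_sd) <- par_names
  structure(list(
    params = params,
    param_sd = param_sd,
    residual_norm = res$sse,
    n_used = n,
    n_excluded = n_excluded,
    converged = res$converged,
    n_iterations = res$iterations
  ), class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("Global fit of the ping-pong substrate-inhibition rate law\n")
  v <- as.numeric(x$params)
  for (nm in names(x$param_sd)) {
    cat(sprintf("  %-9s = %.6g +/- %.3g %s\n", nm, v[[nm]], x$param_sd[[nm]],
                if (nm == "k_cat") "/s" else "uM"))
  }
  if (!is.finite(v[["K_i"]])) cat("  K_i       = Inf (inhibition disabled)\n")
  cat(sprintf("  SSR = %.4g (uM/s)^2 over %d points (%d excluded); converged: %s\n",
              x$residual_norm, x$n_used, x$n_excluded, x$converged))
  invisible(x)
}

#' Initial rate of a progression curve by linear least squares
#'
#' Ordinary least-squares slope of the observable over a time window,
#' the standard way a plate-reader trace is reduced to a reaction velocity.
#'
#' @param curve a [progress_curve()].
#' @param window numeric length-2 time interval (s) within the curve domain;
#'   `NULL` uses the whole curve.
#' @return list with `slope` (observable units per s), `intercept`,
#'   `r_squared` and `n` points used.
#' @export
fit_initial_rate <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "progress_curve"))
  t <- curve$times; y <- curve$values
  if (is.null(window)) window <- range(t)
  if (length(window) != 2L || window[1L] >= window[2L])
    stop("window must be an increasing length-2 time interval")
  if (window[1L] < min(t) || window[2L] > max(t))
    stop("window [", window[1L], ", ", window[2L], "] outside curve domain [",
         min(t), ", ", max(t), "]")
  sel <- t >= window[1L] & t <= window[2L]
  if (sum(sel) < 3L) stop("need >= 3 points in the fitting window")
  fit <- ols_line(t[sel], y[sel])
  c(fit[c("slope", "intercept", "r_squared")], list(n = sum(sel)))
}
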