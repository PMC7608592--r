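# Shared numerical helpers: seeded evaluation, a small Levenberg-Marquardt
# least-squares optimiser (used by global_fit and fit_zz_exchange), ordinary
# least squares on a window, and longest-linear-segment selection.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with `set.seed(seed)` in effect and restores the caller's RNG
#' state afterwards, so generators are bit-reproducible functions of
#' `(parameters, seed)` without clobbering the session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# Forward-difference Jacobian of a residual function.
num_jacobian <- function(fn, par, r0 = NULL, eps = sqrt(.Machine$double.eps)) {
  if (is.null(r0)) r0 <- fn(par)
  p <- length(par)
  J <- matrix(0, length(r0), p)
  for (j in seq_len(p)) {
    h <- eps * max(abs(par[j]), 1)
    pj <- par
    pj[j] <- pj[j] + h
    J[, j] <- (fn(pj) - r0) / h
  }
  J
}

# Levenberg-Marquardt minimisation of sum(fn(par)^2).
# fn returns the residual vector. Returns par, sse, J (at optimum),
# converged flag and iteration count. Pure R; adequate for the small
# (<= 6 parameter) problems in this package.
lm_least_squares <- function(par, fn, maxit = 400L, ftol = 1e-15, ptol = 1e-13,
                             max_step = Inf) {
  r <- fn(par)
  if (any(!is.finite(r))) stop("residuals not finite at starting values")
  sse <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0L
  while (iter < maxit) {
    iter <- iter + 1L
    J <- num_jacobian(fn, par, r)
    g <- crossprod(J, r)          # half-gradient
    A <- crossprod(J)
    dA <- pmax(diag(A), 1e-30)
    accepted <- FALSE
    for (k in 1:40) {
      step <- tryCatch(
        solve(A + lambda * diag(dA, nrow = length(par)), -g),
        error = function(e) NULL
      )
      if (!is.null(step)) {
        step <- pmin(pmax(as.vector(step), -max_step), max_step)
        par_try <- par + step
        r_try <- fn(par_try)
        sse_try <- if (all(is.finite(r_try))) sum(r_try^2) else Inf
        if (sse_try <= sse) {
          rel_dsse <- (sse - sse_try) / max(sse, 1e-300)
          rel_dpar <- max(abs(step) / pmax(abs(par), 1))
          par <- par_try; r <- r_try; sse <- sse_try
          lambda <- max(lambda / 10, 1e-12)
          accepted <- TRUE
          if (rel_dsse < ftol || rel_dpar < ptol || sse < 1e-300) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!accepted || converged) break
  }
  J <- num_jacobian(fn, par, r)
  list(par = par, sse = sse, residuals = r, jacobian = J,
       converged = converged || sse < 1e-300, iterations = iter)
}

# Covariance of LM parameters: residual-variance-scaled (J^T J)^-1.
lm_covariance <- function(J, sse, n, p) {
  dof <- max(n - p, 1L)
  sigma2 <- sse / dof
  A <- crossprod(J)
  cov <- tryCatch(chol2inv(chol(A)), error = function(e) {
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-12
    sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  })
  sigma2 * cov
}

# OLS fit over index range; returns slope, intercept, r_squared.
# A window with (numerically) zero variance in y is treated as perfectly
# linear with slope 0 (r_squared = 1).
ols_line <- function(t, y) {
  n <- length(t)
  stopifnot(n >= 2)
  tm <- mean(t); ym <- mean(y)
  sxx <- sum((t - tm)^2)
  sxy <- sum((t - tm) * (y - ym))
  syy <- sum((y - ym)^2)
  if (syy <= .Machine$double.eps * n * max(ym^2, 1)) {
    return(list(slope = 0, intercept = ym, r_squared = 1))
  }
  slope <- sxy / sxx
  intercept <- ym - slope * tm
  r2 <- max(0, min(1, (sxy^2) / (sxx * syy)))
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Longest contiguous window [i, j] (length >= min_pts) whose OLS fit has
# R^2 >= r2_min; flat windows count as linear. Prefix-sum based O(n^2) scan
# on globally centred data. Returns NULL when no window qualifies.
longest_linear_window <- function(t, y, r2_min = 0.999, min_pts = 5L,
                                  slope_sign = 0) {
  n <- length(t)
  if (n < min_pts) return(NULL)
  tc <- t - mean(t); yc <- y - mean(y)
  cx  <- cumsum(tc);      cy  <- cumsum(yc)
  cxx <- cumsum(tc * tc); cyy <- cumsum(yc * yc); cxy <- cumsum(tc * yc)
  at <- function(c, i) if (i == 0L) 0 else c[i]
  yscale <- max(abs(yc), 1e-300)
  best <- NULL
  for (i in seq_len(n - min_pts + 1L)) {
    j <- n:(i + min_pts - 1L)
    m <- j - i + 1L
    sx  <- cx[j]  - at(cx,  i - 1L); sy  <- cy[j]  - at(cy,  i - 1L)
    sxx <- cxx[j] - at(cxx, i - 1L); syy <- cyy[j] - at(cyy, i - 1L)
    sxy <- cxy[j] - at(cxy, i - 1L)
    vxx <- sxx - sx^2 / m
    vyy <- syy - sy^2 / m
    vxy <- sxy - sx * sy / m
    slope <- vxy / vxx
    flat <- vyy <= 1e-24 * m * yscale^2
    r2 <- ifelse(flat, 1, pmin(1, pmax(0, vxy^2 / (vxx * vyy))))
    ok <- r2 >= r2_min
    if (slope_sign > 0) ok <- ok & (slope > 0 | flat)
    if (slope_sign < 0) ok <- ok & (slope < 0)
    if (any(ok)) {
      jbest <- j[which(ok)[1L]]   # j descending: first ok is the longest
      len <- jbest - i + 1L
      if (is.null(best) || len > best$len) {
        fit <- ols_line(t[i:jbest], y[i:jbest])
        best <- list(start = i, end = jbest, len = len,
                     slope = fit$slope,
                     intercept = fit$intercept,
                     r_squared = fit$r_squared)
      }
    }
    if (!is.null(best) && best$len >= n - i + 1L) break  # cannot improve
  }
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a
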