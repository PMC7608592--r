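# Adaptive Rosenbrock (ode23s-type) integrator. A stiff-capable solver is
# needed because the reaction scheme mixes rate constants spanning ~5 orders
# of magnitude (sub-second phosphorylation vs multi-second isomerisation vs
# hour-scale hydrolysis); no stiff ODE package is assumed to be available.
#
# The method is the 2(3) L-stable Rosenbrock pair of Shampine & Reichelt
# (the MATLAB ode23s scheme) with a forward-difference Jacobian refreshed
# every step. Linear conservation laws c'y (enzyme, glucose and phosphate
# moieties) satisfy c'f(y) = 0 identically, hence c'J = 0 even for the
# finite-difference Jacobian, and every stage preserves them to roundoff.

ode23s_d   <- 1 / (2 + sqrt(2))
ode23s_e32 <- 6 + sqrt(2)

# rhs: function(y) -> dy/dt (autonomous). t_grid: strictly increasing, first
# element is the initial time. Returns matrix length(t_grid) x length(y0).
ode23s_integrate <- function(rhs, y0, t_grid, rtol = 1e-8, atol = 1e-12,
                             max_steps = 2e6) {
  n <- length(y0)
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive")
  out <- matrix(NA_real_, length(t_grid), n,
                dimnames = list(NULL, names(y0)))
  out[1L, ] <- y0
  y <- as.numeric(y0)
  t <- t_grid[1L]
  t_end <- t_grid[length(t_grid)]
  h <- (t_end - t) / 1e3
  Idn <- diag(n)
  steps <- 0L
  next_i <- 2L
  f0 <- rhs(y)
  while (next_i <= length(t_grid)) {
    target <- t_grid[next_i]
    hstep <- min(h, target - t)
    repeat {
      steps <- steps + 1L
      if (steps > max_steps)
        stop(sprintf("ode23s: step limit reached at t = %.6g s", t))
      # Jacobian at (t, y)
      J <- matrix(0, n, n)
      for (j in seq_len(n)) {
        dy <- sqrt(.Machine$double.eps) * max(abs(y[j]), atol)
        yp <- y; yp[j] <- yp[j] + dy
        J[, j] <- (rhs(yp) - f0) / dy
      }
      W <- Idn - (hstep * ode23s_d) * J
      Winv <- tryCatch(solve(W), error = function(e) NULL)
      if (is.null(Winv)) { hstep <- hstep / 4; next }
      k1 <- Winv %*% f0
      f1 <- rhs(y + 0.5 * hstep * k1)
      k2 <- Winv %*% (f1 - k1) + k1
      ynew <- y + hstep * as.vector(k2)
      f2 <- rhs(ynew)
      k3 <- Winv %*% (f2 - ode23s_e32 * (k2 - f1) - 2 * (k1 - f0))
      err <- (hstep / 6) * (k1 - 2 * k2 + k3)
      sk <- atol + rtol * pmax(abs(y), abs(ynew))
      errnorm <- sqrt(mean((err / sk)^2))
      if (is.finite(errnorm) && errnorm <= 1) {
        t <- t + hstep
        y <- ynew
        f0 <- f2
        fac <- if (errnorm > 0) 0.8 * errnorm^(-1/3) else 5
        h <- hstep * min(5, max(0.2, fac))
        break
      }
      fac <- if (is.finite(errnorm) && errnorm > 0) 0.8 * errnorm^(-1/3) else 0.1
      hstep <- hstep * min(0.9, max(0.1, fac))
      if (hstep < .Machine$double.eps * max(abs(t), 1) * 16)
        stop(sprintf("ode23s: step size underflow at t = %.6g s", t))
    }
    while (next_i <= length(t_grid) && abs(t - t_grid[next_i]) <=
             .Machine$double.eps * 32 * max(abs(t), 1)) {
      out[next_i, ] <- y
      next_i <- next_i + 1L
    }
  }
  out
}
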