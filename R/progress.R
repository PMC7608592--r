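# Progression-curve containers and reduction to lag times, steady-state
# rates, observed rate constants and apparent dephosphorylation rates.

progress_kinds <- c("absorbance", "concentration", "normalised_integral")

#' Progression curve
#'
#' A timestamped observable trace: A340 absorbance (AU), a concentration
#' (uM), or a dimensionless normalised 31P integral.
#'
#' @param times times (s), strictly increasing, finite.
#' @param values observable values, finite, same length as `times`.
#' @param kind one of `"absorbance"`, `"concentration"`,
#'   `"normalised_integral"`.
#' @return an object of class `progress_curve`.
#' @export
progress_curve <- function(times, values,
                           kind = c("concentration", "absorbance",
                                    "normalised_integral")) {
  kind <- match.arg(kind)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have the same length")
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("times and values must be finite")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(times = times, values = values, kind = kind),
            class = "progress_curve")
}

#' @export
print.progress_curve <- function(x, ...) {
  cat(sprintf("Progress curve (%s): %d points, t = [%.4g, %.4g] s, value range [%.4g, %.4g]\n",
              x$kind, length(x$times), min(x$times), max(x$times),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.progress_curve <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values, kind = x$kind,
             stringsAsFactors = FALSE)
}

#' Lag time and steady-state rate of a progression curve
#'
#' Quantifies a hysteretic lag: slides a window of `window_frac` of the
#' points along the curve, takes the window of maximal slope as the
#' steady-state segment, fits a line there, and reports its slope as the
#' steady-state rate and its x-intercept (clamped at the curve start, i.e.
#' lag >= 0, measured from the first time point) as the lag time. A curve
#' that rises immediately extrapolates through its origin and gets lag ~ 0;
#' slow activation pushes the intercept out.
#'
#' @param curve a [progress_curve()], increasing overall (a decreasing curve
#'   is the wrong observable direction and is an error).
#' @param window_frac sliding-window width as a fraction of the number of
#'   points, in (0, 1]; default 0.1.
#' @return an object of class `lag_result`: `lag_time` (s), `steady_rate`
#'   (observable units per s), `window` (time bounds of the fitted segment),
#'   `r_squared`.
#' @export
detect_lag <- function(curve, window_frac = 0.1) {
  stopifnot(inherits(curve, "progress_curve"))
  t <- curve$times; y <- curve$values
  n <- length(t)
  if (n < 10L) stop("need >= 10 points to detect a lag")
  if (window_frac <= 0 || window_frac > 1) stop("window_frac must be in (0, 1]")
  if (y[n] < y[1L] && all(diff(y) <= 0))
    stop("curve is monotone decreasing: wrong observable direction for lag detection")
  w <- max(3L, as.integer(ceiling(window_frac * n)))
  # slope of every width-w window via prefix sums
  cx <- cumsum(t); cy <- cumsum(y); cxx <- cumsum(t * t); cxy <- cumsum(t * y)
  i <- seq_len(n - w + 1L); j <- i + w - 1L
  at0 <- function(c, k) c(0, c)[k + 1L]
  sx <- cx[j] - at0(cx, i - 1L); sy <- cy[j] - at0(cy, i - 1L)
  sxx <- cxx[j] - at0(cxx, i - 1L); sxy <- cxy[j] - at0(cxy, i - 1L)
  slopes <- (w * sxy - sx * sy) / (w * sxx - sx^2)
  best <- which.max(slopes)
  sel <- best:(best + w - 1L)
  fit <- ols_line(t[sel], y[sel])
  if (fit$slope <= 0)
    stop("maximal-slope segment is not increasing: no steady-state rise found")
  x_int <- -fit$intercept / fit$slope
  structure(list(
    lag_time = max(0, x_int - t[1L]),
    steady_rate = fit$slope,
    window = c(t[sel[1L]], t[sel[w]]),
    r_squared = fit$r_squared
  ), class = "lag_result")
}

#' @export
print.lag_result <- function(x, ...) {
  cat(sprintf("Lag %.4g s; steady rate %.4g /s units; window [%.4g, %.4g] s (R^2 = %.5f)\n",
              x$lag_time, x$steady_rate, x$window[1L], x$window[2L],
              x$r_squared))
  invisible(x)
}

# Longest linear segment selector shared by kobs_from_p31 and
# apparent_dephos_rate.
auto_linear_segment <- function(t, y, r2_min, min_pts, slope_sign = 0) {
  longest_linear_window(t, y, r2_min = r2_min, min_pts = min_pts,
                        slope_sign = slope_sign)
}

#' Observed rate constant from a 31P G6P time course
#'
#' Fits the linear steady-state portion of the normalised G6P integral and
#' converts its slope (fraction/s) to a per-enzyme turnover constant:
#' `k_obs = slope * substrate_total / E_T` (1/s). The segment is chosen
#' automatically as the longest window with linear-fit R^2 at or above
#' `r2_min`, or given explicitly as time bounds.
#'
#' @param curve a [progress_curve()] of kind `"normalised_integral"` (G6P
#'   fraction).
#' @param substrate_total total phosphosugar pool (uM) used to normalise.
#' @param E_T total enzyme concentration (uM), > 0.
#' @param segment `"auto"` (default) or numeric length-2 time bounds (s).
#' @param r2_min linearity threshold for automatic selection, default 0.999.
#' @return list with `k_obs` (1/s), `slope` (fraction/s), `window` (s),
#'   `r_squared`.
#' @export
kobs_from_p31 <- function(curve, substrate_total, E_T,
                          segment = "auto", r2_min = 0.999) {
  stopifnot(inherits(curve, "progress_curve"))
  if (curve$kind != "normalised_integral")
    stop("curve kind must be 'normalised_integral'")
  if (E_T <= 0) stop("E_T must be positive")
  if (substrate_total <= 0) stop("substrate_total must be positive")
  t <- curve$times; y <- curve$values
  if (identical(segment, "auto")) {
    win <- auto_linear_segment(t, y, r2_min = r2_min, min_pts = 5L)
    if (is.null(win))
      stop("no linear segment with R^2 >= ", r2_min,
           " found; supply segment = c(t_lo, t_hi) manually")
    sel <- win$start:win$end
  } else {
    if (!is.numeric(segment) || length(segment) != 2L)
      stop("segment must be 'auto' or numeric time bounds c(t_lo, t_hi)")
    sel <- which(t >= segment[1L] & t <= segment[2L])
    if (length(sel) < 3L) stop("fewer than 3 points in the requested segment")
  }
  fit <- ols_line(t[sel], y[sel])
  list(k_obs = fit$slope * substrate_total / E_T,
       slope = fit$slope,
       window = c(t[sel[1L]], t[sel[length(sel)]]),
       r_squared = fit$r_squared)
}

#' Apparent dephosphorylation rate from agent depletion
#'
#' The apparent first-order dephosphorylation constant of the phospho-enzyme
#' is read out from the rate at which free phosphorylating agent is consumed
#' at steady state: `rate = -slope / E_T`, where the slope (uM/s, negative)
#' is fitted on the initial steady-state linear portion of the free-agent
#' concentration trace (longest linear window with negative slope starting
#' in the first quarter of the curve; a brief pre-steady-state transient is
#' thereby skipped).
#'
#' @param curve a [progress_curve()] of the free-agent concentration (uM),
#'   decreasing over its initial segment.
#' @param E_T total enzyme concentration (uM), default 200 (the 0.2 mM NMR
#'   assay concentration).
#' @param r2_min linearity threshold, default 0.999.
#' @return list with `rate` (1/s), `slope` (uM/s), `window` (s),
#'   `r_squared`.
#' @export
apparent_dephos_rate <- function(curve, E_T = 200, r2_min = 0.999) {
  stopifnot(inherits(curve, "progress_curve"))
  if (E_T <= 0) stop("E_T must be positive")
  t <- curve$times; y <- curve$values
  n <- length(t)
  if (n < 5L) stop("need >= 5 points")
  if (y[min(n, max(3L, n %/% 4L))] >= y[1L] &&
      max(y) - min(y) <= .Machine$double.eps * 8 * max(abs(y), 1))
    stop("curve shows no depletion: cannot measure a dephosphorylation rate")
  win <- auto_linear_segment(t, y, r2_min = r2_min, min_pts = 5L,
                             slope_sign = -1)
  if (is.null(win) || win$start > ceiling(n / 4))
    stop("no initial decreasing linear segment found (curve nondecreasing?)")
  list(rate = -win$slope / E_T,
       slope = win$slope,
       window = c(t[win$start], t[win$end]),
       r_squared = win$r_squared)
}

#' Convert an absorbance trace to concentration
#'
#' Inverse Beer-Lambert: `[X] (uM) = 1e6 * A / (epsilon * path)`.
#'
#' @param curve a [progress_curve()] of kind `"absorbance"`.
#' @param epsilon molar extinction coefficient (1/(M cm)), default 6220
#'   (NADH at 340 nm).
#' @param path optical path length (cm), default 1.
#' @return a [progress_curve()] of kind `"concentration"` (uM).
#' @export
absorbance_to_concentration <- function(curve, epsilon = 6220, path = 1) {
  stopifnot(inherits(curve, "progress_curve"))
  if (curve$kind != "absorbance") stop("curve kind must be 'absorbance'")
  if (epsilon <= 0 || path <= 0)
    stop("extinction coefficient and path length must be positive")
  progress_curve(curve$times, 1e6 * curve$values / (epsilon * path),
                 kind = "concentration")
}
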