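# Slow-exchange NMR computations: combined amide shift differences,
# conformer populations from duplicated peaks, two-site ZZ-exchange
# modelling and fitting, proline cis/trans classification from 13C-beta
# shifts.

#' Amide peak record
#'
#' One backbone amide resonance: residue number and type, 1H and 15N
#' chemical shifts, intensity, and which slow-exchange state it belongs to.
#'
#' @param residue residue sequence number (integer).
#' @param resname one-letter residue code.
#' @param dH 1H shift (ppm), plausibility window 5-13.
#' @param dN 15N shift (ppm), plausibility window 100-140.
#' @param intensity peak intensity (arbitrary units), >= 0.
#' @param state `"A"`, `"B"` or `"other"`.
#' @return a one-row data frame with columns `residue, resname, state,
#'   dH_ppm, dN_ppm, intensity`.
#' @export
amide_peak <- function(residue, resname, dH, dN, intensity = 1,
                       state = c("A", "B", "other")) {
  state <- match.arg(state)
  if (intensity < 0) stop("intensity must be >= 0")
  if (dH < 5 || dH > 13) stop("1H shift ", dH, " ppm outside plausible window [5, 13]")
  if (dN < 100 || dN > 140) stop("15N shift ", dN, " ppm outside plausible window [100, 140]")
  data.frame(residue = as.integer(residue), resname = resname, state = state,
             dH_ppm = dH, dN_ppm = dN, intensity = intensity,
             stringsAsFactors = FALSE)
}

#' Combined 1H/15N chemical-shift difference
#'
#' Weighted Euclidean distance between two amide peaks of the same residue:
#' \deqn{\Delta\delta = \sqrt{(\delta_{H,X}-\delta_{H,Y})^2 +
#'   (0.12\,(\delta_{N,X}-\delta_{N,Y}))^2}}
#' The 0.12 nitrogen weight compensates for the wider 15N shift range.
#'
#' @param x,y amide peak records ([amide_peak()] rows or lists with
#'   `residue`, `dH_ppm`, `dN_ppm`); vectorised when both are multi-row
#'   tables aligned by row.
#' @param nitrogen_weight weighting of the 15N dimension, default 0.12.
#' @return combined shift difference(s), ppm.
#' @examples
#' a <- amide_peak(113, "A", dH = 8.10, dN = 120.0, state = "A")
#' b <- amide_peak(113, "A", dH = 8.20, dN = 121.0, state = "B")
#' combined_shift_difference(a, b)  # sqrt(0.01 + 0.0144)
#' @export
combined_shift_difference <- function(x, y, nitrogen_weight = 0.12) {
  if (!all(x$residue == y$residue))
    stop("peaks belong to different residues (",
         paste(x$residue, collapse = ","), " vs ",
         paste(y$residue, collapse = ","), ")")
  sqrt((x$dH_ppm - y$dH_ppm)^2 + (nitrogen_weight * (x$dN_ppm - y$dN_ppm))^2)
}

#' Conformer populations from duplicated peak intensities
#'
#' For every residue observed in both slow-exchange states, the A-state
#' fraction is `I_A / (I_A + I_B)`; the population estimate is the median
#' across residues (with interquartile range), robust to a few overlapped or
#' misassigned peaks. Residues with zero total intensity are skipped.
#'
#' @param peaks a peak table (rows as from [amide_peak()], or
#'   [read_peak_list()]) with columns `residue`, `state`, `intensity`.
#' @return list with `pA`, `pB` (medians, `pA + pB = 1`), `iqr` (of the
#'   per-residue pA), `per_residue` (data frame), `n_residues`.
#' @export
populations_from_intensities <- function(peaks) {
  need <- c("residue", "state", "intensity")
  if (!all(need %in% names(peaks)))
    stop("peak table must have columns: ", paste(need, collapse = ", "))
  ab <- peaks[peaks$state %in% c("A", "B"), , drop = FALSE]
  res <- intersect(unique(ab$residue[ab$state == "A"]),
                   unique(ab$residue[ab$state == "B"]))
  if (!length(res)) stop("no residue has peaks in both states")
  pA <- vapply(res, function(r) {
    ia <- sum(ab$intensity[ab$residue == r & ab$state == "A"])
    ib <- sum(ab$intensity[ab$residue == r & ab$state == "B"])
    if (ia + ib <= 0) NA_real_ else ia / (ia + ib)
  }, 0)
  keep <- !is.na(pA)
  if (!any(keep)) stop("all residues have zero total intensity")
  pA <- pA[keep]; res <- res[keep]
  med <- stats::median(pA)
  list(pA = med, pB = 1 - med,
       iqr = unname(diff(stats::quantile(pA, c(0.25, 0.75)))),
       per_residue = data.frame(residue = res, pA = pA),
       n_residues = length(res))
}

#' Two-site ZZ-exchange intensities
#'
#' Longitudinal two-site exchange with equal relaxation in both states:
#' \deqn{I_{AA}(t) = p_A (p_A + p_B e^{-k_{ex} t}) e^{-R_1 t}}
#' \deqn{I_{BB}(t) = p_B (p_B + p_A e^{-k_{ex} t}) e^{-R_1 t}}
#' \deqn{I_{AB}(t) = I_{BA}(t) = p_A p_B (1 - e^{-k_{ex} t}) e^{-R_1 t}}
#' Total longitudinal order decays as `exp(-R1 t)` and cross peaks are
#' symmetric by construction.
#'
#' @param pA fraction of state A, in (0, 1).
#' @param k_ex exchange rate constant (1/s), >= 0.
#' @param R1 longitudinal relaxation rate (1/s), >= 0.
#' @param t mixing time(s) (s).
#' @return data frame with columns `t_mix_s, I_AA, I_BB, I_AB, I_BA`.
#' @examples
#' zz_intensities(0.7, k_ex = 1.0, R1 = 1.2, t = 0.5)
#' @export
zz_intensities <- function(pA, k_ex, R1, t) {
  if (pA <= 0 || pA >= 1) stop("pA must be in (0, 1)")
  if (k_ex < 0 || R1 < 0) stop("rates must be >= 0")
  pB <- 1 - pA
  ek <- exp(-k_ex * t); er <- exp(-R1 * t)
  data.frame(
    t_mix_s = t,
    I_AA = pA * (pA + pB * ek) * er,
    I_BB = pB * (pB + pA * ek) * er,
    I_AB = pA * pB * (1 - ek) * er,
    I_BA = pA * pB * (1 - ek) * er)
}

#' Fit the two-site ZZ-exchange model
#'
#' Joint least-squares fit of `(amplitude, pA, k_ex, R1)` to the auto- and
#' cross-peak intensity series over mixing time. The two cross-peak series
#' are averaged before fitting (they are identical under the equal-R1
#' model). Degenerate data with all-zero cross peaks return `k_ex = 0` with
#' `degenerate = TRUE` rather than an error. Detailed balance
#' (`k_AB = pB k_ex`, `k_BA = pA k_ex`) is maintained by parameterisation.
#'
#' @param data a data frame (or [gen_zz_dataset()] output) with columns
#'   `t_mix_s, I_AA, I_BB, I_AB, I_BA`; >= 3 mixing times.
#' @return an object of class `exchange_fit`: `k_ex`, `pA`, `R1`,
#'   `amplitude`, `sd` (named), `converged`, `degenerate`, `sse`.
#' @examples
#' d <- zz_intensities(0.7, 0.5, 1.2, c(0.1, 0.3, 0.5, 0.9))
#' fit_zz_exchange(d)
#' @export
fit_zz_exchange <- function(data) {
  need <- c("t_mix_s", "I_AA", "I_BB", "I_AB", "I_BA")
  if (!all(need %in% names(data)))
    stop("ZZ dataset must have columns: ", paste(need, collapse = ", "))
  if (length(unique(data$t_mix_s)) < 3L) stop("need >= 3 mixing times")
  t <- data$t_mix_s
  cross <- (data$I_AB + data$I_BA) / 2
  auto_scale <- max(data$I_AA, data$I_BB)
  if (auto_scale <= 0) stop("auto-peak intensities are all zero")
  if (max(cross) <= 1e-10 * auto_scale) {
    # no exchange detectable
    pA0 <- data$I_AA[1L] / (data$I_AA[1L] + data$I_BB[1L])
    return(structure(list(k_ex = 0, pA = pA0, R1 = NA_real_,
                          amplitude = NA_real_,
                          sd = c(k_ex = NA, pA = NA, R1 = NA, amplitude = NA),
                          converged = TRUE, degenerate = TRUE, sse = NA_real_),
                     class = "exchange_fit"))
  }
  obs <- c(data$I_AA, data$I_BB, cross)
  model <- function(amp, pA, kex, R1) {
    pB <- 1 - pA
    ek <- exp(-kex * t); er <- exp(-R1 * t)
    amp * c(pA * (pA + pB * ek) * er,
            pB * (pB + pA * ek) * er,
            pA * pB * (1 - ek) * er)
  }
  # parameterisation: log amplitude, logit pA, log k_ex, log R1
  unpack <- function(th) list(amp = exp(th[1L]),
                              pA = stats::plogis(th[2L]),
                              kex = exp(th[3L]),
                              R1 = exp(th[4L]))
  resid_fn <- function(th) {
    p <- unpack(th)
    obs - model(p$amp, p$pA, p$kex, p$R1)
  }
  # starting heuristics
  pA0 <- min(max(data$I_AA[1L] / (data$I_AA[1L] + data$I_BB[1L]), 0.05), 0.95)
  tot <- data$I_AA + data$I_BB + 2 * cross
  R10 <- if (all(tot > 0) && length(t) >= 2L)
    max(-ols_line(t, log(tot))$slope, 0.01) else 1
  kex0 <- max(0.5 / max(t), 0.05)
  amp0 <- max(tot[1L] / exp(-R10 * t[1L]), auto_scale)
  th0 <- c(log(amp0), stats::qlogis(pA0), log(kex0), log(R10))
  res <- lm_least_squares(th0, resid_fn)
  p <- unpack(res$par)
  cov_th <- lm_covariance(res$jacobian, res$sse, length(obs), 4L)
  sd_th <- sqrt(pmax(diag(cov_th), 0))
  # delta method to natural scale
  grad <- c(p$amp, p$pA * (1 - p$pA), p$kex, p$R1)
  sd_nat <- setNames(sd_th * grad, c("amplitude", "pA", "k_ex", "R1"))
  structure(list(k_ex = p$kex, pA = p$pA, R1 = p$R1, amplitude = p$amp,
                 sd = sd_nat[c("k_ex", "pA", "R1", "amplitude")],
                 converged = res$converged, degenerate = FALSE,
                 sse = res$sse),
            class = "exchange_fit")
}

#' @export
print.exchange_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("ZZ-exchange fit: no cross-peak intensity; k_ex = 0 (degenerate)\n")
  } else {
    cat(sprintf("ZZ-exchange fit: k_ex = %.4g /s, pA = %.4g, R1 = %.4g /s, amplitude = %.4g (converged: %s)\n",
                x$k_ex, x$pA, x$R1, x$amplitude, x$converged))
  }
  invisible(x)
}

#' Classify an Xaa-Pro peptide bond from the proline 13C-beta shift
#'
#' Proline 13C-beta nuclei in cis peptide bonds resonate 2.0-2.5 ppm
#' downfield of trans. With trans resonances observed up to 31.9 ppm, shifts
#' at or below 32.4 ppm (upper trans bound + 0.5) are called `trans`, at or
#' above 33.9 ppm (+ 2.0) `cis`, and the gap `ambiguous`. The thresholds are
#' a documented heuristic for this shift window, not a universal classifier.
#'
#' @param cbeta_shift proline 13C-beta shift(s), ppm; must lie in 25-40.
#' @param trans_max upper bound of the trans call, default 32.4.
#' @param cis_min lower bound of the cis call, default 33.9.
#' @return character vector in `{"trans", "cis", "ambiguous"}`.
#' @examples
#' classify_proline_isomer(c(31.0, 34.7, 33.0))
#' @export
classify_proline_isomer <- function(cbeta_shift, trans_max = 32.4,
                                    cis_min = 33.9) {
  if (any(!is.finite(cbeta_shift)))
    stop("shifts must be finite")
  if (any(cbeta_shift < 25 | cbeta_shift > 40))
    stop("13C-beta shift outside the proline window [25, 40] ppm")
  ifelse(cbeta_shift <= trans_max, "trans",
         ifelse(cbeta_shift >= cis_min, "cis", "ambiguous"))
}
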