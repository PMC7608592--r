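# Seeded synthetic-data generators. Every generator is a bit-reproducible
# function of (parameters, seed) and produces data with the statistical
# structure the analysis stages assume, so the whole pipeline is testable
# without instrument data.

#' Gaussian noise model for synthetic observables
#'
#' Noise standard deviation for an observable of value `v` is
#' `sqrt((relative_sd * v)^2 + absolute_floor^2)`. The 2% relative default
#' is typical of plate-reader and NMR-integral data.
#'
#' @param relative_sd relative standard deviation (fraction), >= 0.
#' @param absolute_floor absolute noise floor (observable units), >= 0.
#' @param seed integer seed; identical seed implies identical output.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(relative_sd = 0.02, absolute_floor = 0, seed = 1L) {
  if (relative_sd < 0 || absolute_floor < 0)
    stop("noise parameters must be >= 0")
  structure(list(relative_sd = relative_sd, absolute_floor = absolute_floor,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# Add seeded Gaussian noise; truncation at zero (documented small-signal
# bias) keeps rates/intensities physical.
apply_noise <- function(values, noise, truncate_at_zero = TRUE) {
  stopifnot(inherits(noise, "noise_model"))
  if (noise$relative_sd == 0 && noise$absolute_floor == 0) return(values)
  sdv <- sqrt((noise$relative_sd * values)^2 + noise$absolute_floor^2)
  out <- values + stats::rnorm(length(values), 0, sdv)
  if (truncate_at_zero) pmax(out, 0) else out
}

#' Generate a synthetic initial-rate table
#'
#' Full factorial (betaG1P x betaG16BP) grid of initial rates from
#' [evaluate_rate()] with seeded Gaussian noise, in the standard rate-table
#' schema. Defaults reproduce the wild-type plate design: the 11 x 5
#' concentration grid at 1 nM enzyme, in triplicate.
#'
#' @param params generating [kinetic_params()].
#' @param bG1P_list,bG16BP_list concentration lists (uM), positive.
#' @param E_T total enzyme concentration (uM).
#' @param replicates number of replicates per condition.
#' @param noise a [noise_model()].
#' @return data frame with columns
#'   `bG1P_uM, bG16BP_uM, ET_uM, v0_uM_per_s, replicate`.
#' @examples
#' nrow(gen_rate_table(bpgm_params("WT")))  # 11 * 5 * 3 = 165
#' @export
gen_rate_table <- function(params = bpgm_params("WT"),
                           bG1P_list = bpgm_grid("WT")$bG1P,
                           bG16BP_list = bpgm_grid("WT")$bG16BP,
                           E_T = bpgm_grid("WT")$E_T,
                           replicates = 3L,
                           noise = noise_model()) {
  if (!length(bG1P_list) || !length(bG16BP_list) ||
      any(bG1P_list <= 0) || any(bG16BP_list <= 0))
    stop("concentration lists must be nonempty and positive")
  grid <- expand.grid(bG1P_uM = bG1P_list, bG16BP_uM = bG16BP_list,
                      replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE)
  v <- evaluate_rate(params, grid$bG1P_uM, grid$bG16BP_uM, E_T)
  v <- with_seed(noise$seed, apply_noise(v, noise))
  data.frame(bG1P_uM = grid$bG1P_uM, bG16BP_uM = grid$bG16BP_uM,
             ET_uM = E_T, v0_uM_per_s = v, replicate = grid$replicate)
}

#' Generate coupled-assay progression curves for the agent scenarios
#'
#' Simulates the allomorphy scheme for each phosphorylating-agent scenario
#' and returns noisy A340 progression curves. Defaults emulate the standard
#' assay design: 50 uM betaG1P, enzyme starting at the 70:30 A:B
#' equilibrium, agents at 1 mM F16BP, 8 mM acetyl phosphate or 10 uM
#' betaG16BP.
#'
#' @param agents character vector of scenarios to simulate.
#' @param params [kinetic_params()] for the catalytic block.
#' @param E_T total enzyme (uM); the 0.02 uM default is high enough that the
#'   slowest (F16BP) scenario runs to substrate exhaustion within the default
#'   40 min window.
#' @param bG1P initial substrate (uM).
#' @param agent_conc named vector of initial agent concentrations (uM).
#' @param pA_init initial fraction of conformer A.
#' @param t_grid output times (s).
#' @param noise a [noise_model()] applied to the absorbance.
#' @param scheme_overrides named rate overrides passed to
#'   [build_allomorphy_scheme()].
#' @param rtol,atol solver tolerances.
#' @return named list of [progress_curve()]s (kind `"absorbance"`), one per
#'   agent.
#' @export
gen_progress_curves <- function(agents = c("F16BP", "AcP", "bG16BP"),
                                params = bpgm_params("WT"),
                                E_T = 0.02, bG1P = 50,
                                agent_conc = c(F16BP = 1000, AcP = 8000,
                                               bG16BP = 10),
                                pA_init = 0.7,
                                t_grid = seq(0, 2400, by = 2),
                                noise = noise_model(),
                                scheme_overrides = list(),
                                rtol = 1e-8, atol = 1e-12) {
  agents <- match.arg(agents, several.ok = TRUE)
  curves <- lapply(agents, function(ag) {
    sc <- build_allomorphy_scheme(ag, params = params,
                                  overrides = scheme_overrides)
    init <- c(A = pA_init * E_T, B = (1 - pA_init) * E_T, bG1P = bG1P)
    if (ag == "bG16BP") init["bG16BP"] <- agent_conc[[ag]]
    else init["agent"] <- agent_conc[[ag]]
    tr <- integrate_scheme(sc, init, t_grid, rtol = rtol, atol = atol)
    absorbance_observable(tr)
  })
  names(curves) <- agents
  with_seed(noise$seed, {
    lapply(curves, function(cv) {
      progress_curve(cv$times, apply_noise(cv$values, noise), kind = cv$kind)
    })
  })
}

#' Generate a synthetic ZZ-exchange dataset
#'
#' [zz_intensities()] evaluated at the mixing times (default: the standard
#' 100/300/500/900 ms series) plus seeded noise.
#'
#' @param pA fraction of state A.
#' @param k_ex exchange rate constant (1/s).
#' @param R1 longitudinal relaxation rate (1/s).
#' @param mixing_times mixing times (s).
#' @param noise a [noise_model()].
#' @return data frame `t_mix_s, I_AA, I_BB, I_AB, I_BA` (class
#'   `zz_dataset`/`data.frame`).
#' @export
gen_zz_dataset <- function(pA = 0.7, k_ex = 0.5, R1 = 1.2,
                           mixing_times = c(0.1, 0.3, 0.5, 0.9),
                           noise = noise_model()) {
  d <- zz_intensities(pA, k_ex, R1, mixing_times)
  with_seed(noise$seed, {
    for (col in c("I_AA", "I_BB", "I_AB", "I_BA"))
      d[[col]] <- apply_noise(d[[col]], noise)
  })
  class(d) <- c("zz_dataset", "data.frame")
  d
}

#' Generate paired slow-exchange amide peaks
#'
#' Per-residue A/B peak pairs whose intensity ratio encodes the conformer
#' populations, with seeded noise on intensities and random but plausible
#' shift positions; the B-state peak is displaced by Gaussian shift offsets.
#'
#' @param pA fraction of state A.
#' @param n_residues number of residues with doubled peaks.
#' @param shift_offsets list with `dH_sd` and `dN_sd` (ppm), the standard
#'   deviations of the B-state displacement.
#' @param noise a [noise_model()] applied to intensities.
#' @return a peak table (columns `residue, resname, state, dH_ppm, dN_ppm,
#'   intensity`).
#' @export
gen_peak_pairs <- function(pA = 0.7, n_residues = 102L,
                           shift_offsets = list(dH_sd = 0.05, dN_sd = 0.5),
                           noise = noise_model()) {
  if (pA <= 0 || pA >= 1) stop("pA must be in (0, 1)")
  with_seed(noise$seed, {
    residue <- sort(sample(2:210, n_residues))
    resname <- sample(strsplit("ACDEFGHIKLMNQRSTVWY", "")[[1]],
                      n_residues, replace = TRUE)
    dH <- stats::runif(n_residues, 6.5, 9.5)
    dN <- stats::runif(n_residues, 105, 130)
    dH_B <- pmin(pmax(dH + stats::rnorm(n_residues, 0, shift_offsets$dH_sd), 5), 13)
    dN_B <- pmin(pmax(dN + stats::rnorm(n_residues, 0, shift_offsets$dN_sd), 100), 140)
    iA <- apply_noise(rep(pA, n_residues), noise)
    iB <- apply_noise(rep(1 - pA, n_residues), noise)
    rbind(
      data.frame(residue = residue, resname = resname, state = "A",
                 dH_ppm = dH, dN_ppm = dN, intensity = iA,
                 stringsAsFactors = FALSE),
      data.frame(residue = residue, resname = resname, state = "B",
                 dH_ppm = dH_B, dN_ppm = dN_B, intensity = iB,
                 stringsAsFactors = FALSE))
  })
}
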