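# Shared fixtures: noiseless generating tables and perturbed fit starts.

wt_truth <- bpgm_params("WT")
p146a_truth <- bpgm_params("P146A")

noiseless_table <- function(variant = "WT") {
  g <- bpgm_grid(variant)
  gen_rate_table(bpgm_params(variant), g$bG1P, g$bG16BP, g$E_T,
                 replicates = 1L, noise = noise_model(0))
}

perturbed_start <- function(truth, factor = 3) {
  kinetic_params(truth$k_cat * factor, truth$K_bG1P * factor,
                 truth$K_bG16BP * factor,
                 if (is.finite(truth$K_i)) truth$K_i * factor else Inf)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# Direct term-by-term transcription of the printed rate law, kept separate
# from evaluate_rate() as its oracle.
rate_law_oracle <- function(k_cat, K_S, K_I, K_i, S, I, E_T) {
  numerator <- k_cat * E_T * S * I
  term1 <- S * I
  term2 <- K_S * I
  # (K_i + S)/K_i -> 1 as K_i -> infinity (plain ping-pong limit)
  term3 <- K_I * S * (if (is.finite(K_i)) (K_i + S) / K_i else 1)
  numerator / (term1 + term2 + term3)
}

# P146A-mimic scheme for the dephosphorylation assay: conformer-B-only
# enzyme (trans isomer locked, so no A pool, no trans->cis step).
dephos_assay_scheme <- function() {
  build_allomorphy_scheme("F16BP", params = bpgm_params("P146A"),
                          overrides = list(k_AB = 0, k_BA = 0, k_isoP = 0,
                                           k_phos_A = 0, k_act_G16BP = 0,
                                           f_release = 0))
}
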