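# The two-conformer allomorphy reaction scheme and its ODE realisation.
#
# Substrate-free enzyme interconverts slowly between conformer A (cis
# K145-P146, the catalytically competent form) and conformer B (trans).
# Phosphorylating agents act on both conformers; only the phosphorylated A
# form (A_P) carries mutase flux. betaG16BP generated during turnover
# activates either conformer directly to A_P, which is what terminates the
# lag phase ("allomorphy").

#' Default rate constants of the allomorphy scheme
#'
#' First-order constants in 1/s, second-order in 1/(uM s). Literature-anchored
#' values: `k_hyd_AP` 0.06/s (phospho-enzyme hydrolysis of A_P), `k_hyd_BP`
#' 0.003/s (apparent B_P dephosphorylation), `k_isoP` 0.003/s (B_P -> A_P
#' isomerisation), A:B interconversion at k_ex = 0.1/s split 70:30
#' (`k_AB` 0.03, `k_BA` 0.07). Phosphorylation constants are calibration
#' values chosen to respect the observed qualitative ordering (acetyl
#' phosphate inherently faster than F16BP; betaG16BP activation fastest);
#' see the methods vignette.
#'
#' @return named numeric vector of rate constants.
#' @export
default_scheme_rates <- function() {
  c(k_AB = 0.03, k_BA = 0.07,
    k_isoP = 0.003,
    k_hyd_AP = 0.06, k_hyd_BP = 0.003,
    k_phos_A = NA_real_, k_phos_B = NA_real_,  # set per agent in the builder
    k_act_G16BP = 1.0,
    f_release = 0.02)
}

agent_phos_defaults <- c(F16BP = 5e-5, AcP = 5e-4)

#' Build the two-conformer allomorphy reaction scheme
#'
#' Assembles the reaction set for a chosen phosphorylating agent:
#' * `A <-> B` conformer exchange (`k_AB`, `k_BA`);
#' * for agents `"F16BP"` and `"AcP"`: `A + agent -> A_P + byproduct`
#'   (`k_phos_A`) and `B + agent -> B_P + byproduct` (`k_phos_B`), the
#'   byproduct being fructose monophosphate or acetate respectively;
#' * `B_P -> A_P` isomerisation (`k_isoP`), and hydrolysis `A_P -> A + Pi`
#'   (`k_hyd_AP`), `B_P -> B + Pi` (`k_hyd_BP`);
#' * the condensed catalytic block: betaG1P -> G6P at the ping-pong
#'   substrate-inhibition rate with total enzyme replaced by `[A_P]`;
#' * a betaG16BP seeding branch of the covalent cycle,
#'   `A_P + betaG1P -> A + betaG16BP`, at rate
#'   `f_release * k_cat * [A_P] * S / (K_bG1P + S)`;
#' * betaG16BP activation `A + betaG16BP -> A_P + G6P` and
#'   `B + betaG16BP -> A_P + G6P` (`k_act_G16BP`): phosphorylation by the
#'   intermediate stabilises conformer A regardless of the starting
#'   conformation, so this route never produces B_P.
#'
#' For `agent_kind = "bG16BP"` the activation route is the only
#' phosphorylation pathway (no `agent`/`byproduct` species; supply the agent
#' as initial `bG16BP`).
#'
#' NADH is carried as a bookkeeping species produced 1:1 with G6P
#' (instantaneous-coupling assumption for the G6P dehydrogenase assay).
#'
#' @param agent_kind `"F16BP"`, `"AcP"` or `"bG16BP"`.
#' @param params [kinetic_params()] for the catalytic block.
#' @param overrides named list/vector overriding entries of
#'   [default_scheme_rates()] (including `k_phos_A`, `k_phos_B`,
#'   `k_act_G16BP`, `f_release`).
#' @return an object of class `scheme_spec`: species, rates, reaction list
#'   and a moiety composition matrix used for conservation checks.
#' @examples
#' sc <- build_allomorphy_scheme("F16BP")
#' sc$species
#' @export
build_allomorphy_scheme <- function(agent_kind = c("F16BP", "AcP", "bG16BP"),
                                    params = bpgm_params("WT"),
                                    overrides = list()) {
  agent_kind <- match.arg(agent_kind)
  validate_kinetic_params(params)
  rates <- default_scheme_rates()
  if (agent_kind != "bG16BP") {
    rates[["k_phos_A"]] <- agent_phos_defaults[[agent_kind]]
    rates[["k_phos_B"]] <- agent_phos_defaults[[agent_kind]]
  }
  if (length(overrides)) {
    ov <- unlist(overrides)
    bad <- setdiff(names(ov), names(rates))
    if (length(bad)) stop("unknown rate override(s): ", paste(bad, collapse = ", "))
    if (any(!is.finite(ov) | ov < 0)) stop("rate overrides must be nonnegative")
    rates[names(ov)] <- ov
  }
  has_agent <- agent_kind != "bG16BP"
  species <- c("A", "B", "A_P", "B_P", "bG1P", "bG16BP", "G6P",
               if (has_agent) c("agent", "byproduct"), "Pi", "NADH")

  # moiety composition: enzyme / glucose / phosphate count per species
  comp <- rbind(
    enzyme    = c(A = 1, B = 1, A_P = 1, B_P = 1, bG1P = 0, bG16BP = 0,
                  G6P = 0, agent = 0, byproduct = 0, Pi = 0, NADH = 0),
    glucose   = c(A = 0, B = 0, A_P = 0, B_P = 0, bG1P = 1, bG16BP = 1,
                  G6P = 1, agent = 0, byproduct = 0, Pi = 0, NADH = 0),
    phosphate = c(A = 0, B = 0, A_P = 1, B_P = 1, bG1P = 1, bG16BP = 2,
                  G6P = 1,
                  agent = if (agent_kind == "F16BP") 2 else 1,
                  byproduct = if (agent_kind == "F16BP") 1 else 0,
                  Pi = 1, NADH = 0))
  comp <- comp[, species, drop = FALSE]

  rx <- function(name, reactants, products, kind = "mass_action", k = NULL) {
    list(name = name, reactants = reactants, products = products,
         kind = kind, k = k)
  }
  reactions <- list(
    rx("A_to_B", c(A = 1), c(B = 1), k = "k_AB"),
    rx("B_to_A", c(B = 1), c(A = 1), k = "k_BA"),
    rx("BP_to_AP", c(B_P = 1), c(A_P = 1), k = "k_isoP"),
    rx("AP_hydrolysis", c(A_P = 1), c(A = 1, Pi = 1), k = "k_hyd_AP"),
    rx("BP_hydrolysis", c(B_P = 1), c(B = 1, Pi = 1), k = "k_hyd_BP"),
    rx("catalysis", c(bG1P = 1), c(G6P = 1, NADH = 1), kind = "catalytic"),
    rx("G16BP_release", c(A_P = 1, bG1P = 1), c(A = 1, bG16BP = 1),
       kind = "release"),
    rx("activation_A", c(A = 1, bG16BP = 1), c(A_P = 1, G6P = 1, NADH = 1),
       k = "k_act_G16BP"),
    rx("activation_B", c(B = 1, bG16BP = 1), c(A_P = 1, G6P = 1, NADH = 1),
       k = "k_act_G16BP"))
  if (has_agent) {
    reactions <- c(reactions, list(
      rx("phos_A", c(A = 1, agent = 1), c(A_P = 1, byproduct = 1),
         k = "k_phos_A"),
      rx("phos_B", c(B = 1, agent = 1), c(B_P = 1, byproduct = 1),
         k = "k_phos_B")))
  }

  structure(list(
    agent_kind = agent_kind,
    species = species,
    rates = rates,
    params = params,
    reactions = reactions,
    composition = comp,
    byproduct_name = switch(agent_kind, F16BP = "fructose monophosphate",
                            AcP = "acetate", bG16BP = "glucose 6-phosphate")
  ), class = "scheme_spec")
}

#' @export
print.scheme_spec <- function(x, ...) {
  cat(sprintf("Allomorphy reaction scheme (agent: %s, byproduct: %s)\n",
              x$agent_kind, x$byproduct_name))
  cat(sprintf("  %d species, %d reactions\n", length(x$species),
              length(x$reactions)))
  fin <- x$rates[is.finite(x$rates)]
  cat("  rates:", paste(sprintf("%s=%.3g", names(fin), fin), collapse = ", "),
      "\n")
  invisible(x)
}

# Derivative function dy/dt for a scheme; y named by species.
scheme_rhs <- function(scheme) {
  species <- scheme$species
  nsp <- length(species)
  nr <- length(scheme$reactions)
  N <- matrix(0, nsp, nr, dimnames = list(species, NULL))
  for (i in seq_len(nr)) {
    r <- scheme$reactions[[i]]
    N[names(r$reactants), i] <- N[names(r$reactants), i] - r$reactants
    N[names(r$products), i]  <- N[names(r$products), i] + r$products
  }
  ridx <- lapply(scheme$reactions, function(r)
    rep(match(names(r$reactants), species), times = r$reactants))
  kval <- vapply(scheme$reactions, function(r)
    if (r$kind == "mass_action") scheme$rates[[r$k]] else NA_real_, 0)
  kinds <- vapply(scheme$reactions, `[[`, "", "kind")
  p <- scheme$params
  f_rel <- scheme$rates[["f_release"]]
  i_S  <- match("bG1P", species)
  i_I  <- match("bG16BP", species)
  i_AP <- match("A_P", species)
  Kinv <- if (is.finite(p$K_i)) 1 / p$K_i else 0

  function(y) {
    yp <- pmax(y, 0)  # rate evaluation only; state itself is never clipped
    v <- numeric(nr)
    for (i in seq_len(nr)) {
      v[i] <- switch(kinds[i],
        mass_action = kval[i] * prod(yp[ridx[[i]]]),
        catalytic = {
          S <- yp[i_S]; I <- yp[i_I]
          den <- S * I + p$K_bG1P * I + p$K_bG16BP * S * (1 + S * Kinv)
          if (den > 0) p$k_cat * yp[i_AP] * S * I / den else 0
        },
        release = {
          S <- yp[i_S]
          f_rel * p$k_cat * yp[i_AP] * S / (p$K_bG1P + S)
        })
    }
    as.vector(N %*% v)
  }
}

#' Integrate an allomorphy scheme
#'
#' Stiff-capable (Rosenbrock) integration of the mass-action ODE system on a
#' fixed output grid. Deterministic for fixed inputs. Concentrations are
#' clipped at zero in the returned trajectory only; the solver state is never
#' clipped.
#'
#' @param scheme a `scheme_spec` from [build_allomorphy_scheme()].
#' @param init named numeric vector of initial concentrations (uM); species
#'   not named start at 0; unknown names are an error.
#' @param t_grid strictly increasing output times (s) starting at the initial
#'   time.
#' @param rtol,atol relative/absolute (uM) solver tolerances.
#' @return an object of class `trajectory`: `times`, `conc` (time x species
#'   matrix, uM), and solver metadata.
#' @examples
#' sc <- build_allomorphy_scheme("bG16BP")
#' tr <- integrate_scheme(sc, c(A = 0.7e-3, B = 0.3e-3, bG1P = 50, bG16BP = 10),
#'                        t_grid = seq(0, 10, by = 1))
#' @export
integrate_scheme <- function(scheme, init, t_grid, rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(scheme, "scheme_spec"))
  bad <- setdiff(names(init), scheme$species)
  if (length(bad))
    stop("unknown species in initial conditions: ", paste(bad, collapse = ", "),
         if (scheme$agent_kind == "bG16BP" && "agent" %in% bad)
           " (for the bG16BP scheme supply the agent as 'bG16BP')" else "")
  if (any(init < 0)) stop("initial concentrations must be nonnegative")
  y0 <- setNames(numeric(length(scheme$species)), scheme$species)
  y0[names(init)] <- init
  conc <- ode23s_integrate(scheme_rhs(scheme), y0, t_grid,
                           rtol = rtol, atol = atol)
  conc[conc < 0] <- 0  # clip negatives at output only
  structure(list(
    times = t_grid,
    conc = conc,
    scheme_hash = scheme_digest(scheme),
    solver = list(method = "rosenbrock23", rtol = rtol, atol = atol)
  ), class = "trajectory")
}

# Cheap structural fingerprint of a scheme (no external digest dependency).
scheme_digest <- function(scheme) {
  s <- paste(scheme$agent_kind,
             paste(scheme$species, collapse = ","),
             paste(sprintf("%s=%.17g", names(scheme$rates), scheme$rates),
                   collapse = ","),
             paste(sprintf("%.17g", as.numeric(scheme$params)), collapse = ","),
             sep = ";")
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 2^31
}

#' Conservation-law drift of a trajectory
#'
#' Maximum relative drift, over time, of each conserved moiety total
#' (enzyme, glucose, phosphate) implied by the scheme's composition matrix.
#'
#' @param traj a [integrate_scheme()] trajectory.
#' @param scheme the `scheme_spec` that produced it.
#' @return named numeric vector of maximum relative drifts.
#' @export
conservation_drift <- function(traj, scheme) {
  stopifnot(inherits(traj, "trajectory"), inherits(scheme, "scheme_spec"))
  totals <- traj$conc %*% t(scheme$composition)
  drift <- apply(totals, 2L, function(x) {
    ref <- x[1L]
    if (abs(ref) < 1e-300) max(abs(x)) else max(abs(x - ref) / abs(ref))
  })
  setNames(drift, rownames(scheme$composition))
}

#' Absorbance observable of a trajectory (coupled assay)
#'
#' Converts the NADH time course to A340 by Beer-Lambert:
#' `A = epsilon * path * [NADH]` with uM -> M conversion. Under the
#' instantaneous-coupling assumption NADH tracks cumulative G6P production,
#' so the curve is monotone nondecreasing.
#'
#' @param traj a trajectory containing `NADH`.
#' @param epsilon_NADH molar extinction coefficient (1/(M cm)), default 6220.
#' @param path optical path length (cm), default 1.
#' @return a [progress_curve()] of kind `"absorbance"`.
#' @export
absorbance_observable <- function(traj, epsilon_NADH = 6220, path = 1) {
  stopifnot(inherits(traj, "trajectory"))
  if (epsilon_NADH <= 0 || path <= 0)
    stop("extinction coefficient and path length must be positive")
  if (!"NADH" %in% colnames(traj$conc))
    stop("trajectory has no NADH species")
  A <- epsilon_NADH * path * traj$conc[, "NADH"] * 1e-6
  progress_curve(traj$times, A, kind = "absorbance")
}

#' 31P observables of a trajectory
#'
#' Normalised betaG1P and G6P integral time courses: each concentration is
#' divided by the initial total phosphosugar pool
#' `[betaG1P](0) + [G6P](0)`, mirroring normalised peak integrals from a
#' 31P equilibration experiment.
#'
#' @param traj a trajectory containing `bG1P` and `G6P`.
#' @return list of two [progress_curve()]s of kind `"normalised_integral"`:
#'   `bG1P` and `G6P`.
#' @export
p31_observable <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  need <- c("bG1P", "G6P")
  if (!all(need %in% colnames(traj$conc)))
    stop("trajectory must contain bG1P and G6P")
  norm <- traj$conc[1L, "bG1P"] + traj$conc[1L, "G6P"]
  if (norm <= 0) stop("zero initial phosphosugar pool: cannot normalise")
  list(
    bG1P = progress_curve(traj$times, traj$conc[, "bG1P"] / norm,
                          kind = "normalised_integral"),
    G6P  = progress_curve(traj$times, traj$conc[, "G6P"] / norm,
                          kind = "normalised_integral"))
}
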