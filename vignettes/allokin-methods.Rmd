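---
title: "Methods: modelling allomorphic regulation of beta-phosphoglucomutase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling allomorphic regulation of beta-phosphoglucomutase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokin)
```

## The system

beta-Phosphoglucomutase (betaPGM) from *Lactococcus lactis* isomerises
beta-glucose 1-phosphate (betaG1P) to glucose 6-phosphate (G6P) via a
beta-glucose 1,6-bisphosphate (betaG16BP) intermediate, shuttling the
phosphoryl group through a covalent phospho-aspartate (D8) enzyme form. The
substrate-free enzyme is not one species: it populates two conformers in slow
(multi-second) exchange that differ in the cis/trans isomer of the K145-P146
peptide bond — conformer A (cis, catalytically competent when phosphorylated)
and conformer B (trans, much less active). Which phosphorylating agent primes
the enzyme therefore decides the shape of a progress curve: the reaction
intermediate betaG16BP ("full" activator) phosphorylates both conformers
straight to the active A^P form and the assay starts at full speed, whereas
partial agents (fructose 1,6-bisphosphate, F16BP; acetyl phosphate, AcP)
phosphorylate each conformer in place, strand a fraction of the enzyme as the
sluggish B^P species, and produce a pronounced lag while the betaG16BP pool
builds up autocatalytically. This substrate-driven selection between
conformers with different rate-limiting steps is called allomorphy.

The package implements four computational layers: (1) the steady-state rate
law and its global fit, (2) an ODE model of the two-conformer scheme with
assay observables, (3) progression-curve reduction (lags, steady rates,
observed and apparent rate constants), and (4) slow-exchange NMR analysis.
A synthetic-data layer generates every input the pipeline consumes.

## The rate law

Initial rates follow a ping-pong bi-bi mechanism adapted for betaG1P
substrate inhibition:

$$v_0 = \frac{k_{cat}\,[E_T]\,S\,I}
{S\,I + K_{S}\,I + K_{I}\,S\left(\frac{K_i + S}{K_i}\right)},
\qquad S = [\beta\text{G1P}],\ I = [\beta\text{G16BP}]$$

with $K_S$ and $K_I$ the Michaelis constants of betaG1P and betaG16BP and
$K_i$ the betaG1P inhibition constant. Setting $K_i = \infty$ recovers plain
ping-pong kinetics. Units are fixed package-wide as uM, s, uM/s; $k_{cat}$ is
in 1/s with enzyme in uM.

`global_fit()` minimises the unweighted sum of squared rate residuals over
all grid conditions simultaneously. Choices a user should know about:

* **Log-parameter optimisation.** All four constants are strictly positive;
  fitting their logarithms keeps the problem smooth and unconstrained. A
  per-iteration step clamp (factor ~20) stops the weakly determined $K_i$
  direction from running away before the other parameters settle. With this,
  noiseless grids are recovered to better than 0.1% from any start within a
  factor of 10 of the truth.
* **Uniform weighting.** The source protocol does not state a weighting;
  ordinary least squares is assumed.
* **Replicates.** The default fits per-condition means (mirroring mean-of-
  triplicate fitting); `average_replicates = FALSE` fits every point.
* **Uncertainties.** Jacobian-based covariance scaled by residual variance,
  delta-method-transformed back from log space; a seeded residual bootstrap
  (default 1000 resamples) is available because the original uncertainty
  method is unstated.
* **High-betaG16BP filtering.** Above ~10 uM betaG16BP the model stops
  describing wild-type plate data (back reaction plus a betaG16BP-Mg2+
  multimeric interaction), so those points were excluded in the original
  wild-type analysis. This is exposed as `filter_max_bG16BP` (default
  `NULL`: no filtering, matching the variant analysis, where no exclusion is
  stated).
* **$E_T$ is fixed**, never floated: rates are measured at known enzyme
  concentrations.

The published parameter sets used as generating truths are available via
`bpgm_params()` / `bpgm_grid()`: wild type $k_{cat}$ 382 /s, $K_S$ 91 uM,
$K_I$ 8.5 uM, $K_i$ 1510 uM on an 11 x 5 grid at 1 nM enzyme; P146A 19.2 /s,
157 uM, 175 uM, 933 uM on an 11 x 6 grid at 100 nM enzyme.

## The reaction scheme

`build_allomorphy_scheme()` condenses the two-conformer cycle into a
mass-action ODE system:

* `A <-> B` (k_AB, k_BA), the cis/trans conformer exchange;
* `A + agent -> A_P + byproduct`, `B + agent -> B_P + byproduct` for the
  partial agents (byproduct: fructose monophosphate for F16BP, acetate for
  AcP);
* `B_P -> A_P` (k_isoP), the trans-to-cis isomerisation of the
  phospho-enzyme;
* hydrolysis `A_P -> A + Pi` (k_hyd_AP), `B_P -> B + Pi` (k_hyd_BP);
* a condensed catalytic block: betaG1P -> G6P at the full rate law with
  $[E_T]$ replaced by $[A^P]$ — this avoids inventing unpublished
  microscopic on/off rates while keeping the saturation behaviour exact;
* a betaG16BP seeding branch `A_P + betaG1P -> A + betaG16BP` at rate
  $f_{release}\,k_{cat}\,[A^P]\,S/(K_S+S)$. This is the fraction of covalent
  half-cycles in which the intermediate escapes to solution instead of
  re-reacting in place. It is deliberately nonzero at zero betaG16BP — it is
  what lets a partial-agent assay bootstrap its intermediate pool, and hence
  what creates the lag timescale;
* activation `A|B + betaG16BP -> A_P + G6P` (k_act_G16BP), present in every
  scheme: phosphorylation by the intermediate stabilises conformer A
  regardless of the starting conformation. For `agent_kind = "bG16BP"` it is
  the *only* phosphorylation route, so that pathway can never produce B^P —
  matching the observation that B^P is absent when the intermediate is the
  agent.

The seeding/rebinding granularity was an open design point; a single
one-step branch with a release fraction was chosen over an explicit
release-rebind pair because the data the model must reproduce (lag ordering,
steady rates) cannot distinguish them. The betaG16BP-Mg2+ multimeric
attenuation at high intermediate concentrations and F16BP anomer
interconversion are acknowledged but not modelled; a minor agent-bound
A:F16BP complex is likewise omitted.

### Rate-constant defaults

Literature-anchored values: `k_hyd_AP` 0.06 /s, `k_hyd_BP` 0.003 /s (equal
to the apparent dephosphorylation constant measured via F16BP depletion),
`k_isoP` 0.003 /s (the lower bound on the trans-to-cis conversion of B^P),
and A:B exchange at $k_{ex}$ = 0.1 /s split 70:30 (`k_AB` 0.03, `k_BA` 0.07)
— inside the measured bracket 0.003-1.0 /s.

No phosphorylation rate constants are published, so these are calibration
values chosen once to respect the qualitative constraints: AcP is inherently
a much faster phosphorylating agent than F16BP; phosphorylation by 50 mM
F16BP outruns A^P hydrolysis (0.06 /s) but stays below the 140 Hz shift
difference; and the intermediate activates fastest. Defaults: `k_phos`
(F16BP) 5e-5, `k_phos` (AcP) 5e-4, `k_act_G16BP` 1.0 /(uM s), `f_release`
0.02. With the generator's default 20 nM enzyme these give lag times of
roughly 920 s (F16BP), 19 s (AcP) and ~0 s (betaG16BP) for the standard
50 uM betaG1P assay — the observed ordering. The absolute lag values are a
property of this stated parameterisation, not a fitted quantity; no rate
constant here was tuned to any figure.

### Numerics

The system is stiff (rate constants span ~5 orders of magnitude), and no
stiff-ODE package is assumed available, so integration uses a self-contained
L-stable Rosenbrock 2(3) pair (the classic `ode23s` scheme) with adaptive
steps, forward-difference Jacobians, `rtol` 1e-8 and `atol` 1e-12 uM.
Because every conserved moiety (enzyme, glucose, phosphate) is a left null
vector of the stoichiometry, and the finite-difference Jacobian inherits
that null space exactly, conservation holds to roundoff regardless of step
size — the test suite checks 1e-8 relative. Negative concentrations are
clipped only in the returned trajectory, never fed back to the solver. The
two-state analytic relaxation is reproduced to <1e-6.

Observables: A340 by Beer-Lambert on an NADH bookkeeping species produced
1:1 with G6P (the G6P-dehydrogenase coupling is treated as instantaneous —
the coupling enzyme is in large excess); 31P readouts as betaG1P and G6P
concentrations normalised by the initial phosphosugar pool. Evaporation
artefacts after substrate depletion are not modelled.

## Progression-curve reduction

* **Lag time** has no standard quantitative definition in this assay, so
  `detect_lag()` uses the tangent-extrapolation convention: the maximal-slope
  sliding window (default width 10% of points) is fitted with a line whose
  x-intercept, clamped at zero and measured from the curve start, is the lag.
  For the integrated burst model $P(t) = V(t - (1-e^{-kt})/k)$ this
  converges to $1/k$, the natural hysteresis timescale. Lag is invariant to
  time shifts and value rescaling; the steady rate scales linearly.
* **k_obs** from a 31P G6P fraction curve is `slope * substrate_total / E_T`
  (the printed units, 1/s, force the per-enzyme normalisation). The "linear
  steady-state portion" is chosen automatically as the longest window with
  OLS $R^2 \ge$ 0.999 (configurable; the original choice was manual, so
  auto-selection is a reproducible interpretation). Windows with numerically
  zero variance count as linear with slope 0, so a flat curve gives
  k_obs = 0 rather than an error.
* **Apparent dephosphorylation rate** is `-slope / E_T` on the initial
  steady-state linear portion of a free-agent depletion trace (longest
  negative-slope linear window starting in the first quarter of the curve,
  which skips the brief pre-steady-state transient). Default `E_T` 200 uM,
  the NMR assay concentration.
* **Absorbance to concentration** is the inverse Beer-Lambert with the NADH
  extinction coefficient 6220 /(M cm).

## Slow-exchange NMR

* **Combined shift difference**:
  $\Delta\delta = [(\Delta\delta_H)^2 + (0.12\,\Delta\delta_N)^2]^{1/2}$,
  a metric over (1H, 15N) shift pairs.
* **Populations** from doubled peaks: per-residue $p_A = I_A/(I_A+I_B)$,
  aggregated as the median across residues (the original estimator is
  unstated; the median resists overlapped peaks), with interquartile range.
* **ZZ-exchange**: two-site longitudinal exchange with equal $R_1$ in both
  states (same residue, standard simplification; an unequal-$R_1$ variant is
  out of scope):
  $I_{AA} = p_A(p_A + p_B e^{-k_{ex}t})e^{-R_1 t}$,
  $I_{BB} = p_B(p_B + p_A e^{-k_{ex}t})e^{-R_1 t}$,
  $I_{AB} = I_{BA} = p_A p_B(1 - e^{-k_{ex}t})e^{-R_1 t}$.
  Total longitudinal order decays as $e^{-R_1 t}$; cross peaks are symmetric
  by construction. `fit_zz_exchange()` fits (amplitude, $p_A$, $k_{ex}$,
  $R_1$) jointly to the auto series and the averaged cross series; detailed
  balance is maintained by parameterisation. All-zero cross peaks return
  $k_{ex} = 0$ flagged degenerate — supporting a bound-from-absence reading
  as well as an explicit fit. Noiseless data at the standard
  100/300/500/900 ms mixing times are recovered to 1e-6 relative.
* **Proline cis/trans**: cis 13C-beta resonates 2.0-2.5 ppm downfield of
  trans; with trans observed at 30.4-31.9 ppm the classifier calls trans
  at or below 32.4 ppm (upper trans bound + 0.5), cis at or above 33.9
  (+ 2.0), ambiguous between. These thresholds are a heuristic for this
  shift window, not a universal classifier.

## What the synthetic data does and does not establish

The generators emulate the *designs*: the factorial plate grids with
Gaussian noise (2% relative default, truncated at zero — a small documented
bias at near-zero rates), the three-agent progression assay, the four-point
ZZ series, and doubled-peak intensity lists. They do not emulate baseline
drift, evaporation, anomeric equilibria, peak overlap, or spectral
processing. A green recovery test therefore establishes that the estimators
invert the package's own generating model at the stated noise level — the
correct self-consistency criterion when no raw instrument data are
deposited — and nothing more. Parameter-recovery acceptance runs use
noiseless grids with fits started at 3x the generating values; stochastic
robustness is checked separately over 50 noise seeds (median $k_{cat}$
error < 5% at 2% noise).

## Known limitations

* The condensed catalytic block is exact only in the quasi-steady-state
  sense of the rate law; an elementary-step variant would need unpublished
  microscopic constants.
* Lag magnitudes depend on the calibrated phosphorylation defaults; only
  their ordering is a tested claim.
* The ZZ model assumes equal relaxation in both states.
* `kobs_from_p31`'s longest-linear-window rule can, at the default
  threshold, include part of a gentle onset (underestimating the slope by a
  few percent) or, at very strict thresholds, prefer a flat plateau;
  `segment` bounds override it when judgement is needed.
* 32-bit seeds; generators are reproducible per seed but make no claim of
  reproducibility across R versions' RNG changes.
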