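# allokin

Enzyme allomorphy kinetics and slow-exchange NMR analysis in R.

## What this package is for

beta-Phosphoglucomutase (betaPGM) from *Lactococcus lactis* converts
beta-glucose 1-phosphate (betaG1P) to glucose 6-phosphate (G6P) through a
beta-glucose 1,6-bisphosphate (betaG16BP) intermediate. The substrate-free
enzyme populates two conformers in multi-second exchange — A (cis K145-P146
peptide bond, catalytically competent once phosphorylated) and B (trans,
far less active). Whether an assay shows an immediate fast rate or a long
hysteretic lag depends on which phosphorylating agent primes the enzyme:
the intermediate betaG16BP activates everything straight to the active
A^P form, while partial agents (F16BP, acetyl phosphate) strand enzyme as
the sluggish B^P species until the betaG16BP pool builds up. That
substrate-driven conformer selection is *allomorphy*.

`allokin` is for kineticists and NMR spectroscopists who want to analyse
(or simulate) this class of system:

* **Rate-law fitting** — the ping-pong bi-bi law with betaG1P substrate
  inhibition,

  v0 = kcat·[E_T]·S·I / ( S·I + K_S·I + K_I·S·(K_i + S)/K_i ),

  globally fitted over a (betaG1P x betaG16BP) initial-rate grid in
  log-parameter space with Jacobian or bootstrap uncertainties
  (`evaluate_rate()`, `global_fit()`).
* **Reaction-scheme simulation** — the two-conformer scheme (conformer
  exchange, per-conformer phosphorylation, B^P -> A^P isomerisation,
  hydrolysis, a condensed catalytic block on [A^P], betaG16BP seeding and
  activation) integrated with a built-in stiff Rosenbrock solver, with A340
  and 31P observables (`build_allomorphy_scheme()`, `integrate_scheme()`).
* **Progression-curve analysis** — tangent-extrapolation lag times and
  steady rates, k_obs from 31P time courses, apparent dephosphorylation
  rates from agent depletion, Beer-Lambert conversions (`detect_lag()`,
  `kobs_from_p31()`, `apparent_dephos_rate()`).
* **Slow-exchange NMR** — combined 1H/15N shift differences (nitrogen
  weight 0.12), conformer populations from doubled peaks, two-site
  ZZ-exchange fitting, proline cis/trans classification from 13C-beta
  shifts (`combined_shift_difference()`, `populations_from_intensities()`,
  `fit_zz_exchange()`, `classify_proline_isomer()`).
* **Synthetic data** — seeded generators for every input, so the whole
  pipeline is testable without instrument data (`gen_rate_table()`,
  `gen_progress_curves()`, `gen_zz_dataset()`, `gen_peak_pairs()`).

Units are uM, s and uM/s throughout; column names carry unit suffixes.

## Worked example

Generate a noisy wild-type plate (the published 11 x 5 concentration grid,
1 nM enzyme, triplicate, 2% noise), refit it, and fit a synthetic
ZZ-exchange dataset:

```r
library(allokin)

tab <- gen_rate_table(bpgm_params("WT"), noise = noise_model(0.02, seed = 1))
fit <- global_fit(tab, filter_max_bG16BP = 10)
print(fit)
#> Global fit of the ping-pong substrate-inhibition rate law
#>   k_cat     = 396.902 +/- 3.68 /s
#>   K_bG1P    = 96.1312 +/- 1.46 uM
#>   K_bG16BP  = 8.86313 +/- 0.116 uM
#>   K_i       = 1454.17 +/- 45.1 uM
#>   SSR = 2.736e-05 (uM/s)^2 over 55 points (0 excluded); converged: TRUE

d <- gen_zz_dataset(pA = 0.7, k_ex = 0.5, R1 = 1.2, noise = noise_model(0))
fit_zz_exchange(d)
#> ZZ-exchange fit: k_ex = 0.5 /s, pA = 0.7, R1 = 1.2 /s, amplitude = 1 (converged: TRUE)

classify_proline_isomer(c(31.0, 34.7))
#> [1] "trans" "cis"
```

The refit recovers the generating constants (kcat 382 /s, K_S 91 uM,
K_I 8.5 uM, K_i 1510 uM) to within a few percent at 2% noise — and exactly,
to <0.1%, on noiseless grids. The ZZ fit returns the generating exchange
rate (0.5 /s, below the 1.0 /s slow-exchange bound) from the four standard
mixing times. The 34.7 ppm proline 13C-beta shift classifies as a cis
peptide bond; 31.0 ppm sits in the observed trans range.

A command-line surface wraps the same stages:

```sh
Rscript -e 'quit(status = allokin::allokin_cli())' gen-data --out-dir demo --seed 1
Rscript -e 'quit(status = allokin::allokin_cli())' fit-rates --in demo/rates.csv --out-prefix demo/fit
```

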