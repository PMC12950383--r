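# edam

Donor-only risk scoring of deceased-donor kidneys with the Equitable
Donor Assessment Model (EDAM), plus the full statistical pipeline needed
to derive and validate such a score on transplant registry data.

## The scientific problem

Kidney allocation in the US ranks deceased-donor organs with the Kidney
Donor Profile Index (KDPI), which mixes donor biology with demographic
proxies. EDAM is a donor-only alternative: a fixed linear predictor over
nine donor fields (age, sex, cause of death, BMI, CMV status,
hypertension and diabetes duration, terminal creatinine, proteinuria)
mapped through the inverse complementary log-log link,

    score = 1 − exp(−exp(x'β)),

and stratified into five risk categories at 0.80 / 0.85 / 0.90 / 0.95.
The statistical engine is pseudo-observation regression of the
cumulative incidence of death-censored graft failure in the presence of
the competing event death-with-function: jackknife pseudo-values of the
Aalen-Johansen estimate at a horizon, regressed with a cloglog-link GLM
(working variance 1, HC0 sandwich errors), which approximates Fine-Gray
subdistribution-hazard regression — exponentiated coefficients are
subdistribution hazard ratios.

The package provides:

- `cif_estimate()`, `pseudo_values()` — Aalen-Johansen cumulative
  incidence and exact jackknife pseudo-observations (compiled fast path
  with an R oracle);
- `fit_pseudo_glm()`, `univariable_screen()`, `group_lasso_bic()`,
  `postselection_refit()`, `derive_model()` — the derivation pipeline;
- `edam_coefficients()`, `edam_score()`, `edam_category()` — the frozen
  published 17-term score;
- `ipcw_cindex()`, `bootstrap_cindex()`, `decile_calibration()`,
  `calibration_slope()`, `iecv()`, `pool_random_effects()`,
  `grays_test()`, `reclassification()` — the validation toolkit;
- `simulate_cohort()` — a registry-like synthetic cohort generator with
  a known Fine-Gray outcome process, so every stage is testable without
  registry access;
- a command-line interface (`inst/cli/edam`) with `simulate`, `score`,
  `fit`, `validate` and `reclassify` subcommands.

See the vignette (`vignettes/edam-methods.Rmd`) for the model,
assumptions and numerical choices.

## Worked example

Simulate a cohort under the frozen coefficients, score it, and refit the
model from the synthetic outcomes:

```r
library(edam)

cfg <- sim_config(n = 20000, seed = 1)
cohort <- simulate_cohort(cfg)

scored <- edam_score(cohort)
print(scored)
#> EDAM scores for 20000 donor(s)
#>   score range: 0.5229 - 0.9942
#>   categories: 1:11433 2:4355 3:2864 4:1118 5:230

theta <- pseudo_values(cohort$time, cohort$event, tau = 5)
design <- encode_design(cohort, c("donor_age", "donor_sex",
  "cause_of_death", "donor_bmi", "donor_cmv", "htn_duration",
  "dm_duration", "donor_creatinine", "proteinuria"))
fit <- fit_pseudo_glm(design$X[, names(edam_coefficients())], theta)
print(fit)
#> Pseudo-value cloglog GLM (robust HC0 errors), n = 20000
#>                   term  estimate        se  conf.low conf.high   p.value    shr
#>            (Intercept) -1.553000 0.0754300 -1.701000 -1.405000 3.760e-94 0.2117
#>              donor_age  0.012450 0.0008891  0.010710  0.014190 1.477e-44 1.0130
#>  cause_of_death_stroke  0.195900 0.0334500  0.130400  0.261500 4.712e-09 1.2160
#>  ...
#>       dm_duration_gt10  0.565100 0.0930700  0.382700  0.747500 1.264e-09 1.7600
#>         donor_sex_male -0.129800 0.0277200 -0.184100 -0.075490 2.815e-06 0.8783

ipcw_cindex(scored$score, cohort$time, cohort$event)
#> [1] 0.5719138

iecv(cohort)
#> Internal-external cross-validation over 5 fold(s) at 5 years
#>  fold    n intercept  slope slope_se intercept_se
#>     1 5472  -0.01261 1.0030   0.0968        0.103
#>     2 3651   0.16060 1.1450   0.1200        0.126
#>     3 1785  -0.28040 0.8111   0.1720        0.184
#>     4 3707   0.09524 1.0570   0.1170        0.126
#>     5 5385  -0.26330 0.7333   0.0900        0.098
#>   pooled slope 0.951 (95% CI 0.791-1.111, tau2 0.01977)
#>   pooled intercept -0.0526 (95% CI -0.2268-+0.1215)
```

The refitted coefficients recover the generating (frozen) set within
their robust confidence intervals, and the pooled internal-external
calibration slope is compatible with 1.

The same pipeline from the shell:

```sh
Rscript inst/cli/edam simulate --n 20000 --seed 1 --out cohort.csv
Rscript inst/cli/edam score    --in cohort.csv --out scored.csv
Rscript inst/cli/edam fit      --cohort cohort.csv --out model.json
Rscript inst/cli/edam validate --cohort cohort.csv --out report.json
```

## Scope

KDPI is consumed as an input percentile and never computed. Registry
analyses (the published real-data C-index and calibration numbers)
require UNOS data and are outside this package; the test suite verifies
the statistical properties of every component on synthetic data instead.
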