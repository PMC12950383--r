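---
title: "Methods: pseudo-value estimation of a donor-only kidney quality score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudo-value estimation of a donor-only kidney quality score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deceased-donor kidneys are triaged with an allocation index (KDPI) that
mixes donor biology with demographic proxies. The EDAM score implemented
here is a donor-only alternative: a fixed linear predictor over nine
donor fields, mapped through the inverse complementary log-log link to a
quality score

$$s = 1 - \exp\{-\exp(\eta)\}, \qquad
  \eta = x^\top\beta \ \text{(no intercept)},$$

and stratified into five risk categories at the fixed cut points 0.80,
0.85, 0.90 and 0.95 (boundary values fall in the upper bin). The frozen
17-coefficient set ships as `edam_coefficients()`; exponentiated
coefficients are subdistribution hazard ratios.

## Outcome model

The target of estimation is the cumulative incidence of death-censored
graft failure (event code 1) at a horizon $\tau$, in the presence of the
competing event death with a functioning graft (code 2). Estimation
proceeds in two stages:

1. **Aalen-Johansen pseudo-observations.** `cif_estimate()` computes the
   nonparametric cause-specific cumulative incidence; at tied times
   events are processed before censorings, so
   $\hat S(t) + \sum_k \hat F_k(t) = 1$ holds exactly on the grid.
   `pseudo_values()` then forms the jackknife transform
   $\theta_i(\tau) = n\hat F_1(\tau) - (n-1)\hat F_1^{(-i)}(\tau)$.
   Pseudo-values may fall outside $[0,1]$; with no censoring and no
   competing events they reduce exactly to the indicators
   $1\{T_i \le \tau\}$. The default path is an exact compiled scheme that
   recomputes the leave-one-out estimate once per distinct
   (time, event) pattern; a naive R implementation is retained as its
   in-suite oracle.

2. **Complementary log-log GLM on pseudo-values.** `fit_pseudo_glm()`
   solves $\sum_i D_i^\top(\theta_i - \mu_i) = 0$ with
   $\mu_i = 1 - \exp(-\exp(\eta_i))$ and working variance 1
   (quasi-Normal; a binomial variance would be undefined for
   pseudo-values outside the unit interval). The solver is Gauss-Newton
   with step halving. Standard errors are HC0 sandwich estimates; no
   small-sample correction is applied because intended cohorts are
   large. This regression approximates Fine-Gray subdistribution-hazard
   regression at the horizon, so $e^{\hat\beta}$ is reported as an SHR.

## Variable selection

`derive_model()` chains univariable screening (group Wald test at
$\alpha = 0.05$, multilevel factors as one block), a group LASSO, and an
unpenalized post-selection refit. The LASSO stage is a one-step
linearization: the penalized working-Gaussian problem is formed at the
unpenalized solution and solved by block coordinate descent in
within-group orthonormalized coordinates, where each block update is the
closed-form group soft-threshold. The $\lambda$ grid is 100 log-spaced
points from the data-derived $\lambda_{\max}$ (smallest value zeroing
every group) down to $\lambda_{\max} \cdot 10^{-4}$; the reported
selection minimizes $\mathrm{BIC} = n\log(\mathrm{RSS}/n) +
\mathrm{df}\log n$ with df the count of nonzero coefficients plus one
for the intercept. Only the selected set matters downstream — the
reported model is always the unpenalized refit. Continuous predictors
enter linearly; `fit_diagnostics_loess()` provides a visual linearity
check but no automatic spline refit is performed.

## Validation toolkit

- **Discrimination**: `ipcw_cindex()` is an inverse probability of
  censoring weighted Harrell's C with weights $1/\hat G(T_i^-)^2$ from
  the Kaplan-Meier censoring distribution; without censoring it equals
  classical Harrell's C exactly. `bootstrap_cindex()` adds a
  bias-corrected percentile interval.
- **Calibration**: `decile_calibration()` regresses observed mean
  pseudo-values on mean predicted risk across ten rank groups;
  `calibration_slope()` refits the cloglog GLM on a model's linear
  predictor (exactly equivariant: halving the predictor doubles the
  slope).
- **Transportability**: `iecv()` performs leave-one-region-out
  cross-validation over five geography-aligned super-regions
  (`super_region_fold()`), pooling fold calibrations with
  DerSimonian-Laird random effects (`pool_random_effects()`, via
  `metafor`).
- **Group comparison**: `grays_test()` (via `cmprsk`) compares
  cause-specific cumulative incidence across score categories;
  `logrank_test()` handles the death-censored low-risk comparison.
- **Reclassification**: `reclassification()` cross-tabulates KDPI bands
  against score quintiles and contrasts the 10-year graft-failure
  incidence of the standard (KDPI < 0.20) and extended (score < 0.80,
  KDPI ≥ 0.20) low-risk pools.

## What the synthetic generator emulates

`simulate_cohort()` draws covariates from marginals matched to a
contemporary US deceased-donor registry (truncated normals for ages and
BMI, a mean-matched lognormal for terminal creatinine, tabulated
category frequencies, gamma laws for waiting and cold ischemia times, a
zero-inflated law for cPRA). Donor sex is not tabulated in such
registry summaries; P(male) = 0.60 is this package's own default. Fields
are drawn independently — real registries have correlated covariates,
era effects and center effects, none of which are modelled.

Outcomes follow the Fine-Gray mixture
$$F_1(t \mid x) = 1 - \bigl[1 - p\,(1 - e^{-t})\bigr]^{\exp(x^\top\beta)},$$
whose cloglog transform is linear in $x^\top\beta$ at every $t$, so the
pseudo-value GLM is correctly specified and targets the generating
coefficients exactly — the property the recovery tests exploit. The
cause indicator is Bernoulli in $F_1(\infty \mid x)$, cause-1 times
follow by inverse transform, competing deaths and random censoring are
exponential, and follow-up is administratively truncated. The defaults
(`p_base = 0.25`, `death_rate = 0.03`/y, `censor_rate = 0.05`/y,
`admin_horizon = 15` y) are this package's own design choices tuned for
a realistic event mix (roughly half censored, with graft failure more
common than competing death); they are not registry estimates. Age and
BMI are centered at their marginal means inside the simulated linear
predictor only, which leaves every slope unchanged and keeps the mixture
mass away from numerical overflow. Ties resolve events before
censorings, matching the estimator's convention.

`add_synthetic_kdpi()` fabricates a KDPI-like percentile from the rank
of the donor linear predictor plus noise. It is a correlated stand-in
for testing the reclassification report; the real KDPI formula is out of
scope and never computed.

## Numerical choices and limitations

- Pseudo-value horizon defaults to 5 years; category cut points and the
  frozen coefficients are fixed constants.
- The score is a monotone risk index, not an absolute risk: the
  published equation has no intercept, so its level is arbitrary and
  `predicted_cif_curve()` re-anchors it when absolute incidence is
  needed.
- HC0 sandwich errors, working variance 1, Gauss-Newton with step
  halving to tolerance 1e-10 on the scaled gradient.
- `unos_region` is drawn uniformly in simulation, so super-region folds
  are exchangeable; real regional case-mix differences are not emulated.
- Problem sizes in the test-suite (for example n = 20,000 recovery
  replicates) are this package's own choices balancing statistical
  resolution against desk-scale runtime.

## A worked example

```{r example}
library(edam)

cfg <- sim_config(n = 20000, seed = 1)
cohort <- simulate_cohort(cfg)

scored <- edam_score(cohort)
table(scored$category)

theta <- pseudo_values(cohort$time, cohort$event, tau = 5)
design <- encode_design(cohort, c("donor_age", "donor_sex",
                                  "cause_of_death", "donor_bmi",
                                  "donor_cmv", "htn_duration",
                                  "dm_duration", "donor_creatinine",
                                  "proteinuria"))
fit <- fit_pseudo_glm(design$X[, names(edam_coefficients())], theta)
print(fit)

ipcw_cindex(scored$score, cohort$time, cohort$event)
iecv(cohort)
```
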