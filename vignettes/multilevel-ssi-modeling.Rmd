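---
title: "Multilevel modelling of surgical site infection risk with ssiml"
author: "ssiml authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel modelling of surgical site infection risk with ssiml}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Surgical site infection (SSI) surveillance networks collect one record per
surgical procedure, nested in wards, nested in hospitals, with a binary
30-day infection outcome and a set of patient-level risk factors (ASA
score, wound contamination class, surgery duration, follow-up length, and
so on). Risk indicators built from single-level logistic models — notably
the standardized infection ratio (SIR), the ratio of observed to
case-mix-expected infections in a ward — ignore the clustering of patients
in wards. `ssiml` implements the multilevel alternative: Bayesian
hierarchical logistic regression with ward (and optionally hospital)
random effects, the median odds ratio (MOR) as the heterogeneity summary,
and validation machinery to quantify how much ward information improves
discrimination over the single-level reference.

Because national surveillance records are confidential, the package ships
a synthetic-cohort generator whose defaults reproduce the published
marginal structure of the 2011 French national SSI surveillance 20% sample
(62 280 patients, 502 wards, 151 hospitals, 1% crude incidence). All
analyses in the test suite and the acceptance script run end-to-end on
synthetic cohorts.

## The models

For patient $i$ in ward $j$ (hospital $k$), with covariate vector
$x_{ij}$ and follow-up indicator $z_{ij}$ (1 if follow-up $\ge$ 15 days):

* **Model 1 (empty)** — $\mathrm{logit}\,\pi_{ij} = \beta_0 + v_k + u_{0j}$,
  no covariates; partitions outcome variance across levels. Fitted by
  `fit_model1_empty()`.
* **Model 2 (random intercept)** —
  $\mathrm{logit}\,\pi_{ij} = \beta_0 + \beta' x_{ij} + u_{0j}$; covariate
  effects common to all wards. `fit_model2_intercept()`.
* **Model 3 (random coefficient)** —
  $\mathrm{logit}\,\pi_{ij} = \beta_0 + \beta' x_{ij} + u_{0j} + u_{15j} z_{ij}$,
  with $(u_{0j}, u_{15j}) \sim N_2(0, \Omega)$,
  $\Omega = \begin{pmatrix}\sigma^2_{00} & \sigma_{01}\\ \sigma_{01} & \sigma^2_{11}\end{pmatrix}$;
  the follow-up effect varies by ward. `fit_model3_slope()`.

The hospital level is retained only when a likelihood-ratio test of its
variance component — referred to the 50:50 mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ appropriate on the boundary of the
parameter space (`test_level_variance()`) — is significant at 0.05.
Candidate covariates enter the multivariate models after univariate
ward-random-intercept screening at p < 0.20 (`univariate_screen()`).

### Heterogeneity: the median odds ratio

For a cluster variance $\sigma^2$ on the log-odds scale,
$\mathrm{MOR} = \exp\!\big(\sqrt{2\sigma^2}\,\Phi^{-1}(0.75)\big)$:
the median, over random pairs of wards, of the odds ratio between the
higher- and the lower-risk ward. It equals 1 under homogeneity and is
independent of outcome prevalence. Under model 3 the effective ward
variance differs by follow-up stratum: $\sigma^2_{00}$ for follow-up
< 15 days and $\sigma^2_{00} + 2\sigma_{01} + \sigma^2_{11}$ for
$\ge$ 15 days (`stratum_variance()`, `stratified_mor()`).

Two conventions needed fixing where the field leaves a choice. The point
MOR applies the formula to the **posterior mean** of the variance
(configurable to the median via `stratified_mor(point = "median")`). The
interval applies the formula to the 2.5th/97.5th percentiles of the
variance draws and is labelled 95%; variance draws and MOR are monotone,
so this is the equal-tailed credibility interval of the MOR itself.

## Estimation: adaptive Metropolis-within-Gibbs

`fit_mcmc()` implements the sampler. Per iteration:

* the fixed-effect block $\beta$ is updated by one multivariate
  random-walk Metropolis step whose proposal covariance comes from the
  single-level ML logistic fit (also the chain initializer), with a global
  scale adapted toward 23% acceptance during burn-in;
* translation moves propose $\beta_0 \to \beta_0 + \delta$ with
  $u_{0j} \to u_{0j} - \delta$ for all wards (likewise for the slope
  coefficient against $u_{15j}$, and the intercept against hospital
  effects). These leave the likelihood unchanged and remove the strong
  posterior correlation between fixed effects and cluster-effect means
  that otherwise cripples random-walk mixing;
* ward effects $u_{0j}$, $u_{15j}$ and hospital effects $v_k$ are updated
  by simultaneous per-cluster scalar random walks (the likelihood
  factorizes over clusters given $\beta$), with a shared step size adapted
  toward 44% acceptance;
* variance components are drawn by conjugate Gibbs updates:
  inverse-gamma(0.001, 0.001) for scalar variances, inverse-Wishart
  (identity scale, 3 degrees of freedom) for the 2×2 ward covariance.
  Fixed effects have N(0, 10⁶) priors. All hyperparameters are
  configurable through `model_spec(priors = ...)`.

Defaults are burn-in 5 000, 50 000 total iterations, thinning 10. The
recovery analyses in the acceptance script and tests use reduced chains
(burn-in 2 000, 10 000 iterations) on cohorts of 200 wards × 100 patients,
where the posterior summaries are Monte-Carlo stable (effective sample
sizes of several hundred for the ward variance). Likelihood probabilities
are clamped to $[10^{-12}, 1-10^{-12}]$. `summary()` reports posterior
means/SDs, ORs with percentile intervals, two-sided tail probabilities
(`coef_p()`, floored at $2/\text{draws}$), effective sample sizes and
split-chain $\widehat R$, and attaches (and signals) a warning when any
$\widehat R$ exceeds 1.1.

## The synthetic generator

`default_config()` encodes the study conditions:

* binary covariate prevalences equal the published surveillance margins
  (e.g. ASA > 2: 0.174; ambulatory surgery: 0.277; follow-up ≥ 15 days:
  0.650), and the six-category procedure mix their published frequencies;
* covariate log-odds ratios equal the log of the published
  random-coefficient model estimates (e.g. ASA > 2: ln 1.99; ambulatory:
  ln 0.35; follow-up ≥ 15 days: ln 0.19);
* the ward covariance is reverse-engineered from the two published stratum
  MORs through the MOR formula inverse
  (`mor_to_variance()`): $\sigma^2_{00} = 4.112$ (MOR 6.92, follow-up
  < 15 days) and combined variance 1.582 (MOR 3.32, ≥ 15 days). Those two
  constraints leave one degree of freedom; we fixed
  $\sigma^2_{11} = 1.0$ once (hence $\sigma_{01} = -1.765$, a valid,
  strongly negative covariance). No fitted variance components were
  published, so these defaults are inversions, not reported values;
* the intercept −4.85 was calibrated once by Monte-Carlo root-finding
  (`calibrate_intercept()`) to a 1% marginal prevalence;
* the hospital variance defaults to 0 (the hospital level did not
  contribute to outcome variability in the source analysis);
* ward sizes are uniform on 10–250 (mean ≈ 130, matching the surveyed
  wards-of-at-least-10 structure), hospitals carry 2–5 wards.

**What the generator does not emulate.** Covariates are drawn mutually
independently — the surveillance reports only marginals — so the joint
covariate distribution is more informative than real data, where risk
factors correlate (long surgeries cluster with contaminated wounds, ASA,
emergency). Consequences are visible and documented: on synthetic
validation cohorts the single-level reference model discriminates at
AUC ≈ 0.85 and the multilevel model at ≈ 0.95, both roughly 0.11 above the
published real-data values (0.73 and 0.84), while the *improvement* from
ward information (≈ +0.10, p ≪ 0.001) replicates. Passing recovery tests
therefore demonstrate correct estimation under the model's own
assumptions, not real-world discrimination levels. SSI diagnosis timing,
infection depth and mortality are not simulated (they are outcome
descriptors, not model covariates).

## Scaled study conditions

The desk-scale recovery analyses use 200 wards × 100 patients with
generator intercept −3.5 (a higher event rate than the 1% study
prevalence, compensating the reduced cohort size; at 1% a 20 000-patient
cohort carries only ~200 events, too few to locate a ward variance). With
~400 events the posterior-mean ward variance is unbiased across
replicates, with a per-cohort MOR spread of roughly ±15%; the acceptance
script averages three independent replicate cohorts per quantity to
reduce that Monte-Carlo spread. One caveat found in development and left
visible: the follow-up ≥ 15 days stratum variance (1.582) arises by
near-cancellation of $\sigma^2_{00} + 2\sigma_{01} + \sigma^2_{11}$, and
with under one event per ward in that stratum $\sigma_{01}$ and
$\sigma^2_{11}$ shrink toward their priors, inflating that stratum's MOR
by roughly 10–25% at this scale. At higher event rates the same sampler
recovers the full covariance accurately, so this is an information limit
of the scaled design, not an estimation defect.

## Validation, SIR and ROC comparison

`predict_prob()` scores a cohort with a fitted model under three
ward-effect policies: `zero` (fixed effects only), `training`
(posterior-mean effects for wards seen in training, zero otherwise) and
`empirical_bayes` (the default: per-ward posterior-mode effects
re-estimated on the evaluation cohort by penalized logistic regression
with the training coefficients and ward covariance held fixed,
`estimate_ward_effects()`). The published validation AUC on an
independent hospital sample is achievable only if ward information is
exploited, and the source analysis does not state its mechanism; the
empirical-Bayes policy is the natural choice and the other two bracket
it. Note that empirical-Bayes ward effects use the evaluation cohort's
own outcomes at the ward level; the resulting AUC measures case-mix
*plus* ward-history discrimination, exactly as a surveillance network
would apply the model to its participating wards.

`sir_table()` reports per-ward and overall SIRs (observed over expected
counts; an ML logistic model evaluated on its own training data has
overall SIR exactly 1 by the score equations — a property test).
`compare_aucs()` tests two models scored on the same patients: per-curve
standard errors use the closed-form AUC SE with
$Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$; the default comparison engine
computes the covariance of the two AUC estimates from paired placement
values, and an alternative engine uses the classical correlated-curve
recipe with the intermediate correlation taken as the average of the
within-case and within-control Pearson correlations of the paired scores
(the continuous quantity the historical lookup table quantizes).

## Numerical choices and edge cases

* Duration dichotomization uses the type-7 (linear interpolation)
  quantile within procedure type, computed on the analyzed cohort;
  records whose duration is missing keep a missing flag. Follow-up
  dichotomizes with the boundary day (15) in the long class.
* Covariates missing in more than 10% of records are discarded
  (strictly greater than); remaining missingness is handled by complete
  cases per fitted model.
* Hospital subsampling takes `round(fraction × hospitals)` whole
  hospitals; the split is an exact partition, deterministic per seed.
* The empirical-Bayes Newton solver is damped (step-halving on the
  penalized objective): undamped Newton can overshoot for wards with few
  or no events. A singular ward covariance is regularized with a 1e-8
  ridge before inversion.
* Separation guards: constant covariate columns are rejected before
  sampling; a constant outcome is rejected.
* All generation and fitting functions restore the caller's RNG state;
  identical seeds give byte-identical cohorts, chains and reports.

## Pipeline

`run_pipeline()` chains the full analysis — cohort (synthetic or CSV),
ward-size filter (≥ 10), hospital split into analysis and validation
sets, hospital-level test, univariate screening, models 1–3, MOR table,
validation ROC/SIR — and writes `report.json` plus a readable
`report.md`. Stage seeds are fixed offsets of the master seed, so reruns
are byte-identical. A YAML config can override any stage parameter;
`inst/scripts/run_pipeline.R` and `inst/scripts/generate_cohort.R` are
thin command-line wrappers.

## Known limitations

* Independent covariates (above) — discrimination levels on synthetic
  data are optimistic relative to real surveillance data.
* One random slope; no crossed or more deeply nested designs.
* No frequentist REML/adaptive-quadrature fitting (approximate-ML GLMM
  fits are used only for screening and the boundary level test).
* No imputation; no calibration metrics (Brier, Hosmer–Lemeshow).
* The MOR point estimate uses the posterior-mean variance; with
  weakly-identified covariance components (few events per ward) this
  functional inherits the posterior's right skew.
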