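## Level selection and univariate covariate screening via approximate-ML
## generalized linear mixed models (lme4), with the chi-bar-square boundary
## correction for variance components.

glmm_formula <- function(covariates, levels) {
  rhs <- if (length(covariates) > 0L) paste(covariates, collapse = " + ")
         else "1"
  for (lev in levels) {
    rhs <- paste0(rhs, " + (1 | ",
                  switch(lev, ward = "ward_id", hospital = "hospital_id"),
                  ")")
  }
  stats::as.formula(paste("ssi ~", rhs))
}

fit_glmm <- function(cohort, covariates, levels) {
  df <- as.data.frame(cohort)
  if (length(levels) == 0L) {
    stats::glm(glmm_formula(covariates, levels), data = df,
               family = stats::binomial())
  } else {
    lme4::glmer(glmm_formula(covariates, levels), data = df,
                family = stats::binomial(), nAGQ = 0L,
                control = lme4::glmerControl(calc.derivs = FALSE))
  }
}

#' Test the contribution of a random level to outcome variability
#'
#' Likelihood-ratio test between two nested random-level structures fitted
#' by approximate maximum likelihood (Laplace/AGQ0 via `lme4`), with the
#' statistic referred to the 50:50 mixture of a point mass at zero and a
#' chi-square with one degree of freedom, the appropriate reference when a
#' variance is tested on its boundary.
#'
#' @param cohort An `ssi_cohort`.
#' @param levels_full Random levels of the larger model, e.g.
#'   `c("ward", "hospital")`.
#' @param levels_reduced Random levels of the smaller model (a subset of
#'   `levels_full`); `character(0)` means a single-level logistic model.
#' @param covariates Optional covariates shared by both models.
#' @return Two-sided p-value for the extra level's variance.
#' @export
test_level_variance <- function(cohort, levels_full, levels_reduced,
                                covariates = character()) {
  if (!all(levels_reduced %in% levels_full))
    stop("levels_reduced must be a subset of levels_full")
  if (setequal(levels_full, levels_reduced)) return(1)
  full <- fit_glmm(cohort, covariates, levels_full)
  red <- fit_glmm(cohort, covariates, levels_reduced)
  stat <- 2 * (as.numeric(stats::logLik(full)) -
                 as.numeric(stats::logLik(red)))
  if (!is.finite(stat) || stat <= 0) return(1)
  0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Univariate multilevel screening of candidate covariates
#'
#' Fits one ward-random-intercept logistic model per candidate and retains
#' candidates whose coefficient p-value falls below `alpha` (0.20 by
#' default, the conventional pre-selection threshold for multivariate
#' modelling). Multi-category covariates are retained if any non-reference
#' level passes.
#'
#' @param cohort An `ssi_cohort`.
#' @param candidates Covariate names to screen (default
#'   [model_covariates()]).
#' @param alpha Retention threshold (default 0.20).
#' @param engine `"glmm"` (default) uses approximate-ML Wald p-values;
#'   `"mcmc"` fits each univariate model by [fit_mcmc()] and uses the
#'   posterior tail probability [coef_p()].
#' @param mcmc Chain settings for the `"mcmc"` engine.
#' @return List with `retained` (names passing) and `p` (named minimum
#'   p-value per candidate).
#' @export
univariate_screen <- function(cohort, candidates = model_covariates(),
                              alpha = 0.20, engine = c("glmm", "mcmc"),
                              mcmc = list(burn_in = 500L, iterations = 3000L,
                                          thin = 5L, seed = 1L)) {
  engine <- match.arg(engine)
  missing_cand <- setdiff(candidates, names(cohort))
  if (length(missing_cand) > 0L)
    stop("candidate(s) not in cohort: ", paste(missing_cand, collapse = ", "))
  pvals <- vapply(candidates, function(cv) {
    cc <- !is.na(cohort[[cv]])
    sub <- keep_attrs(cohort[cc, , drop = FALSE], cohort)
    if (engine == "glmm") {
      fit <- fit_glmm(sub, cv, "ward")
      ct <- stats::coef(summary(fit))
      min(ct[-1L, "Pr(>|z|)"])
    } else {
      fit <- fit_mcmc(model_spec(cv, levels = "ward", mcmc = mcmc), sub)
      min(apply(fit$beta[, -1L, drop = FALSE], 2L, coef_p))
    }
  }, numeric(1))
  list(retained = candidates[pvals < alpha], p = pvals)
}
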