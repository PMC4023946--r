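## Bernoulli-logit likelihood of the hierarchical model and the design
## matrix shared by the sampler, the predictor and the GLM initializer.

## Numerically stable log(1 + exp(x)).
log1p_exp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

## Design matrix with intercept, binary covariates as-is, and procedure
## dummies against the gastrointestinal reference. Rows with missing values
## in the requested covariates must be removed beforehand.
build_design <- function(cohort, covariates) {
  n <- nrow(cohort)
  cols <- list("(Intercept)" = rep.int(1, n))
  for (cv in covariates) {
    if (cv == "procedure_type") {
      for (lev in procedure_levels()[-1]) {
        cols[[paste0("procedure_", lev)]] <-
          as.numeric(cohort$procedure_type == lev)
      }
    } else {
      cols[[cv]] <- as.numeric(cohort[[cv]])
    }
  }
  do.call(cbind, cols)
}

#' Hierarchical Bernoulli-logit log-likelihood
#'
#' Evaluates `sum_ij [ y_ij log pi_ij + (1 - y_ij) log(1 - pi_ij) ]` with
#' `logit pi_ij = beta . x_ij + v_k + u_0j + u_15j * z_ij`, where `z` is the
#' random-slope covariate (the follow-up >= 15 days indicator in the
#' random-coefficient model). Probabilities are clamped away from 0/1 by
#' `eps` so the value is always finite.
#'
#' @param beta Named coefficient vector including `(Intercept)`; names must
#'   match the design columns built from `covariates`.
#' @param cohort An `ssi_cohort` (complete cases for the used covariates).
#' @param covariates Covariate names defining the fixed-effect design
#'   (default: those implied by `names(beta)`).
#' @param ward_effects Optional named list/vector `u0` (and matrix column
#'   `u15`) per ward: a data frame with `ward_id`, `u0`, optionally `u15`.
#' @param hospital_effects Optional data frame with `hospital_id`, `v`.
#' @param slope_covariate Name of the random-slope covariate (default
#'   `"followup_ge15"`), used when `ward_effects` carries `u15`.
#' @param eps Probability clamp (default 1e-12).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(beta, cohort, covariates = NULL,
                           ward_effects = NULL, hospital_effects = NULL,
                           slope_covariate = "followup_ge15", eps = 1e-12) {
  if (is.null(covariates)) covariates <- covariates_from_beta(names(beta))
  X <- build_design(cohort, covariates)
  if (!setequal(colnames(X), names(beta)))
    stop("beta names do not match the design columns: expected ",
         paste(colnames(X), collapse = ", "))
  eta <- drop(X %*% beta[colnames(X)])
  if (!is.null(ward_effects)) {
    idx <- match(cohort$ward_id, ward_effects$ward_id)
    if (anyNA(idx))
      stop("unknown ward id: ", cohort$ward_id[which(is.na(idx))[1]])
    eta <- eta + ward_effects$u0[idx]
    if (!is.null(ward_effects$u15))
      eta <- eta + ward_effects$u15[idx] *
        as.numeric(cohort[[slope_covariate]])
  }
  if (!is.null(hospital_effects)) {
    idx <- match(cohort$hospital_id, hospital_effects$hospital_id)
    if (anyNA(idx))
      stop("unknown hospital id: ", cohort$hospital_id[which(is.na(idx))[1]])
    eta <- eta + hospital_effects$v[idx]
  }
  p <- pmin(pmax(stats::plogis(eta), eps), 1 - eps)
  sum(cohort$ssi * log(p) + (1 - cohort$ssi) * log1p(-p))
}

## Recover covariate list from coefficient names (procedure dummies fold
## back into procedure_type).
covariates_from_beta <- function(nm) {
  nm <- setdiff(nm, "(Intercept)")
  has_proc <- any(startsWith(nm, "procedure_"))
  cv <- nm[!startsWith(nm, "procedure_")]
  if (has_proc) cv <- c(cv, "procedure_type")
  intersect(model_covariates(), cv)
}

## Per-record Bernoulli log-likelihood given the linear predictor.
ll_point <- function(y, eta) y * eta - log1p_exp(eta)
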