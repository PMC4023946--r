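## Shared fixture builders. All cohorts are generated in code at test time.

zero_beta <- function() {
  b <- default_config()$beta
  stats::setNames(rep(0, length(b)), names(b))
}

## Compact synthetic config: scalar ward/hospital layout, explicit ward
## covariance entries, defaults otherwise taken from the calibrated config.
test_config <- function(n_hospitals = 10L, wards_per_hospital = 2L,
                        patients_per_ward = 30L,
                        sigma00 = 0, sigma01 = 0, sigma11 = 0,
                        hospital_variance = 0, intercept = -3,
                        beta = NULL, missing_rates = NULL, seed = 1L) {
  cfg0 <- default_config()
  if (is.null(beta)) beta <- cfg0$beta
  synthetic_config(
    n_hospitals = n_hospitals,
    wards_per_hospital = wards_per_hospital,
    patients_per_ward = patients_per_ward,
    covariate_prevalences = cfg0$covariate_prevalences,
    procedure_mix = cfg0$procedure_mix,
    beta = beta, intercept = intercept,
    ward_covariance = matrix(c(sigma00, sigma01, sigma01, sigma11), 2L),
    hospital_variance = hospital_variance,
    missing_rates = missing_rates, seed = seed)
}

short_mcmc <- function(seed = 1L, iterations = 3000L, burn_in = 500L,
                       thin = 5L) {
  list(burn_in = burn_in, iterations = iterations, thin = thin, seed = seed)
}

## Hand-built 3-ward cohort with known layout (ward sizes 4, 3, 2).
tiny_cohort <- function() {
  df <- data.frame(
    hospital_id = c(rep("HA", 7), rep("HB", 2)),
    ward_id = c(rep("HA.W1", 4), rep("HA.W2", 3), rep("HB.W1", 2)),
    ssi = c(1, 0, 0, 1, 0, 0, 1, 0, 0),
    gender_female = c(1, 0, 1, 1, 0, 0, 1, 0, 1),
    age_ge65 = c(0, 1, 0, 0, 1, 1, 0, 0, 1),
    asa_gt2 = c(1, 0, 0, 1, 0, 0, 0, 1, 0),
    preop_ge48h = 0,
    altemeier_gt2 = c(0, 0, 1, 0, 0, 0, 0, 0, 0),
    endoscopic = 0,
    duration_gt_p75 = c(1, 0, 0, 1, 1, 0, 0, 0, 0),
    emergency = 0,
    ambulatory = c(0, 1, 0, 0, 0, 1, 0, 0, 1),
    followup_ge15 = c(0, 1, 1, 0, 1, 1, 0, 1, 1),
    procedure_type = c("gastrointestinal", "orthopedic", "gynecologic",
                       "gastrointestinal", "ophthalmic", "other",
                       "cardiovascular", "orthopedic", "gynecologic"),
    stringsAsFactors = FALSE)
  as_cohort(df, provenance = "handmade fixture")
}

## Fabricated fit object for predictor-level tests (no MCMC involved).
fake_fit <- function(beta_means, ward_effects = NULL, ward_cov_means = NULL,
                     slope_covariate = NULL, n_draws = 200L) {
  draws <- matrix(rep(beta_means, each = n_draws), n_draws,
                  length(beta_means),
                  dimnames = list(NULL, names(beta_means)))
  wc <- NULL
  if (!is.null(ward_cov_means)) {
    wc <- matrix(rep(ward_cov_means, each = n_draws), n_draws,
                 length(ward_cov_means),
                 dimnames = list(NULL, names(ward_cov_means)))
  }
  structure(list(beta = draws, ward_cov = wc, hospital_var = NULL,
                 ward_effects = ward_effects,
                 covariates = ssiml:::covariates_from_beta(names(beta_means)),
                 slope_covariate = slope_covariate,
                 n = NA_integer_,
                 J = if (is.null(ward_effects)) 0L else nrow(ward_effects),
                 K = 0L),
            class = "ssiml_fit")
}
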