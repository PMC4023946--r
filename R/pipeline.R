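## End-to-end orchestration: cohort -> preprocessing -> level selection ->
## univariate screening -> random-intercept and random-coefficient models
## -> MOR table -> held-out validation (ROC comparison against a
## single-level reference, per-ward SIR).

default_pipeline_config <- function() {
  list(
    seed = 1L,
    cohort = list(source = "synthetic"),  # or list(source = "file", path =)
    min_ward_size = 10L,
    validation_fraction = 0.5,
    screen_alpha = 0.20,
    level_test_alpha = 0.05,
    keep_hospital_level = NULL,  # NULL = decide by the level test
    mcmc = list(burn_in = 2000L, iterations = 10000L, thin = 10L),
    ward_effect_policy = "empirical_bayes")
}

#' Run the full multilevel SSI analysis pipeline
#'
#' Stages, in order: obtain the cohort (synthetic generation or CSV file);
#' filter small wards; split hospitals into analysis and validation sets;
#' fit the three-level empty model and test the hospital level (dropped
#' when its boundary-mixture p-value is at or above `level_test_alpha`);
#' univariate screening at `screen_alpha`; random-intercept model on the
#' retained covariates; random-coefficient model with a ward-varying
#' follow-up effect; MOR table; validation-cohort prediction, ROC
#' comparison against a single-level reference model, and per-ward SIR.
#' Every stage logs its seed, sample size and runtime. Stage seeds are
#' deterministic offsets of the master seed.
#'
#' @param config A configuration list (see the package vignette), a YAML
#'   file path, or `NULL` for the defaults.
#' @param out_dir Optional directory; when given, the report is written as
#'   `report.json` and `report.md` there.
#' @param quiet Suppress progress logging.
#' @return The report: a list with per-stage results.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_pipeline_config(),
                           if (is.null(config)) list() else config)
  seed <- as.integer(cfg$seed)
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log_msg("[%s] done in %.1fs", name,
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }
  report <- list(config = cfg, seed = seed)

  cohort <- stage("cohort", {
    if (identical(cfg$cohort$source, "file")) read_cohort(cfg$cohort$path)
    else {
      gcfg <- if (!is.null(cfg$cohort$config)) cfg$cohort$config
              else default_config()
      generate_cohort(gcfg, seed = seed)
    }
  })
  log_msg("[cohort] %d patients, %d wards, %d hospitals, prevalence %.2f%%",
          nrow(cohort), length(unique(cohort$ward_id)),
          length(unique(cohort$hospital_id)), 100 * mean(cohort$ssi))

  cohort <- stage("filter_wards",
                  filter_small_wards(cohort, cfg$min_ward_size))
  report$descriptives <- describe_cohort(cohort)

  split <- stage("split", sample_hospitals(
    cohort, fraction = 1 - cfg$validation_fraction, seed = seed + 1L))
  train <- split$sample
  valid <- split$remainder

  sparse <- stage("sparse_variables", drop_sparse_variables(train))
  train <- sparse$cohort
  report$dropped_covariates <- sparse$dropped
  candidates <- setdiff(intersect(model_covariates(), names(train)),
                        sparse$dropped)

  mcmc_train <- function(extra_seed)
    utils::modifyList(cfg$mcmc, list(seed = seed + extra_seed))

  report$model1 <- stage("model1_empty", {
    p_hosp <- test_level_variance(train, c("ward", "hospital"), "ward")
    keep_hosp <- if (!is.null(cfg$keep_hospital_level))
      isTRUE(cfg$keep_hospital_level) else p_hosp < cfg$level_test_alpha
    fit <- fit_model1_empty(train,
                            levels = if (keep_hosp) c("ward", "hospital")
                                     else "ward",
                            mcmc = mcmc_train(2L))
    list(hospital_level_p = p_hosp, hospital_level_kept = keep_hosp,
         summary = summary(fit), mor = stratified_mor(fit))
  })

  screened <- stage("screening",
                    univariate_screen(train, candidates,
                                      alpha = cfg$screen_alpha))
  report$screening <- screened
  covs <- screened$retained

  fit2 <- stage("model2_intercept",
                fit_model2_intercept(train, covs, mcmc = mcmc_train(3L)))
  report$model2 <- list(summary = summary(fit2), mor = stratified_mor(fit2))

  slope_cov <- "followup_ge15"
  fit3 <- stage("model3_slope",
                fit_model3_slope(train, unique(c(covs, slope_cov)),
                                 slope_covariate = slope_cov,
                                 mcmc = mcmc_train(4L)))
  report$model3 <- list(summary = summary(fit3), mor = stratified_mor(fit3))

  if (!is.null(valid)) {
    report$validation <- stage("validation", {
      p_ml <- predict_prob(fit3, valid,
                           ward_effect_policy = cfg$ward_effect_policy)
      ref <- stats::glm(glmm_formula(covariates_from_beta(
        colnames(fit3$beta)), character(0)),
        data = as.data.frame(train), family = stats::binomial())
      vd <- as.data.frame(valid)
      cc <- stats::complete.cases(
        vd[, covariates_from_beta(colnames(fit3$beta)), drop = FALSE])
      p_ref <- rep(NA_real_, nrow(valid))
      p_ref[cc] <- stats::predict(ref, newdata = vd[cc, , drop = FALSE],
                                  type = "response")
      ok <- !is.na(p_ml) & !is.na(p_ref)
      cmp <- compare_aucs(p_ml[ok], p_ref[ok], valid$ssi[ok])
      list(roc = cmp, sir = sir_table(valid, p_ml),
           n_validation = sum(ok))
    })
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, out_dir)
  }
  invisible(report)
}

describe_cohort <- function(cohort) {
  yes <- vapply(binary_covariates(),
                function(cv) mean(cohort[[cv]], na.rm = TRUE), numeric(1))
  proc <- table(cohort$procedure_type) / sum(!is.na(cohort$procedure_type))
  list(n = nrow(cohort),
       n_wards = length(unique(cohort$ward_id)),
       n_hospitals = length(unique(cohort$hospital_id)),
       incidence_pct = crude_incidence_pct(cohort),
       covariate_prevalence = yes,
       procedure_mix = as.numeric(proc),
       short_followup_pct = short_followup_pct(cohort))
}

## Serializes the report: JSON for machines, Markdown tables for reading.
write_report <- function(report, out_dir) {
  slim <- report
  slim$config$cohort$config <- NULL  # matrices don't serialize usefully
  for (m in c("model1", "model2", "model3")) {
    if (!is.null(slim[[m]]$summary)) {
      slim[[m]]$coefficients <- slim[[m]]$summary$coefficients
      slim[[m]]$variance_components <- slim[[m]]$summary$variance_components
      slim[[m]]$summary <- NULL
    }
  }
  if (!is.null(slim$validation)) slim$validation$roc <-
      unclass(slim$validation$roc)
  jsonlite::write_json(slim, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 6, force = TRUE)

  fmt_tab <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.2f", x))
    paste(c(paste("|", paste(names(df), collapse = " | "), "|"),
            paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
            apply(df, 1L, function(r)
              paste("|", paste(r, collapse = " | "), "|"))),
          collapse = "\n")
  }
  md <- c("# Multilevel SSI risk analysis report", "",
          sprintf("Seed: %d. Cohort: %d patients, %d wards, %d hospitals; ",
                  report$seed, report$descriptives$n,
                  report$descriptives$n_wards,
                  report$descriptives$n_hospitals),
          sprintf("crude incidence %.2f%%.", report$descriptives$incidence_pct),
          "")
  md <- c(md, sprintf("Hospital-level variance test p = %.3f (%s).",
                      report$model1$hospital_level_p,
                      if (report$model1$hospital_level_kept)
                        "hospital level retained" else "hospital level dropped"),
          "")
  for (m in c("model1", "model2", "model3")) {
    md <- c(md, paste0("## ", switch(m, model1 = "Model 1 (empty)",
                                     model2 = "Model 2 (random intercept)",
                                     model3 = "Model 3 (random coefficient)")),
            "", fmt_tab(report[[m]]$summary$coefficients), "",
            "MOR:", "", fmt_tab(report[[m]]$mor), "")
  }
  if (!is.null(report$validation)) {
    roc <- report$validation$roc
    md <- c(md, "## Validation", "",
            sprintf(paste0("Multilevel AUC %.2f (SE %.4f) vs single-level ",
                           "AUC %.2f (SE %.4f); z = %.2f, p = %.3g."),
                    roc$auc_a, roc$se_a, roc$auc_b, roc$se_b, roc$z, roc$p),
            "")
  }
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(NULL)
}
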