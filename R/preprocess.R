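## Cohort preparation: ward-size filtering, hospital subsampling,
## sparse-covariate discard, covariate dichotomization.

#' Drop wards with fewer than a minimum number of patients
#'
#' Small clusters yield unstable random-effect estimates; surveillance
#' practice is to restrict multilevel analysis to wards with at least 10
#' patients. Record order is preserved.
#'
#' @param cohort An `ssi_cohort`.
#' @param min_n Minimum ward size (default 10).
#' @return The filtered `ssi_cohort`.
#' @export
filter_small_wards <- function(cohort, min_n = 10L) {
  stopifnot(nrow(cohort) > 0L)
  sizes <- table(cohort$ward_id)
  keep_wards <- names(sizes)[sizes >= min_n]
  if (length(keep_wards) == 0L)
    stop("all wards have fewer than ", min_n, " patients; nothing remains")
  out <- cohort[cohort$ward_id %in% keep_wards, , drop = FALSE]
  rownames(out) <- NULL
  keep_attrs(out, cohort)
}

keep_attrs <- function(out, cohort) {
  attr(out, "provenance") <- attr(cohort, "provenance")
  attr(out, "truth") <- attr(cohort, "truth")
  class(out) <- class(cohort)
  out
}

#' Randomly split a cohort by hospital
#'
#' Samples `round(fraction * n_hospitals)` hospitals without replacement;
#' all wards and patients of a sampled hospital travel together. The two
#' returned cohorts partition the input exactly.
#'
#' @param cohort An `ssi_cohort`.
#' @param fraction Proportion of hospitals to sample, in (0, 1].
#' @param seed Integer seed; the partition is deterministic per seed.
#' @return List with elements `sample` and `remainder` (an empty remainder
#'   is returned as `NULL`).
#' @export
sample_hospitals <- function(cohort, fraction, seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  hospitals <- unique(cohort$hospital_id)
  m <- round(fraction * length(hospitals))
  m <- max(1L, min(length(hospitals), m))
  chosen <- with_seed(seed, sample(hospitals, m))
  in_sample <- cohort$hospital_id %in% chosen
  smp <- keep_attrs(cohort[in_sample, , drop = FALSE], cohort)
  rownames(smp) <- NULL
  rem <- if (all(in_sample)) NULL else {
    r <- keep_attrs(cohort[!in_sample, , drop = FALSE], cohort)
    rownames(r) <- NULL
    r
  }
  list(sample = smp, remainder = rem)
}

#' Discard covariates with excessive missingness
#'
#' Covariates whose missing fraction strictly exceeds `max_missing` are
#' removed from the modelling covariate set (their columns are dropped) and
#' reported; a covariate missing in exactly `max_missing` of records is
#' retained.
#'
#' @param cohort An `ssi_cohort`.
#' @param max_missing Maximum tolerated missing proportion (default 0.10).
#' @return List with elements `cohort` (columns dropped) and `dropped`
#'   (character vector of discarded covariate names).
#' @export
drop_sparse_variables <- function(cohort, max_missing = 0.10) {
  candidates <- intersect(model_covariates(), names(cohort))
  frac <- vapply(candidates, function(cv) mean(is.na(cohort[[cv]])),
                 numeric(1))
  dropped <- candidates[frac > max_missing]
  out <- cohort
  if (length(dropped) > 0L) {
    out <- keep_attrs(
      cohort[, setdiff(names(cohort), dropped), drop = FALSE], cohort)
  }
  list(cohort = out, dropped = dropped)
}

#' Flag surgery durations above the procedure-specific 75th percentile
#'
#' Recomputes `duration_gt_p75` within the input cohort: for each procedure
#' type, the 75th percentile of `duration_minutes` (linear interpolation
#' between order statistics, the `type = 7` quantile definition) is taken
#' over the non-missing durations of that type, and a record is flagged 1
#' iff its duration strictly exceeds it. Missing durations propagate to a
#' missing flag.
#'
#' @param cohort An `ssi_cohort` carrying `duration_minutes`.
#' @param prob Percentile to dichotomize at (default 0.75).
#' @param quantile_type Quantile definition passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return The cohort with `duration_gt_p75` recomputed.
#' @export
dichotomize_duration <- function(cohort, prob = 0.75, quantile_type = 7) {
  if (!"duration_minutes" %in% names(cohort))
    stop("cohort carries no duration_minutes column")
  if (anyNA(cohort$procedure_type))
    stop("procedure_type is missing for some records; cannot stratify")
  dur <- cohort$duration_minutes
  flag <- rep(NA_integer_, nrow(cohort))
  for (lev in levels(cohort$procedure_type)) {
    idx <- which(cohort$procedure_type == lev)
    if (length(idx) == 0L) next
    d <- dur[idx]
    if (all(is.na(d))) next
    q <- stats::quantile(d, probs = prob, na.rm = TRUE, names = FALSE,
                         type = quantile_type)
    flag[idx] <- ifelse(is.na(d), NA_integer_, as.integer(d > q))
  }
  out <- cohort
  out$duration_gt_p75 <- flag
  keep_attrs(out, cohort)
}

#' Dichotomize follow-up duration at a day cutoff
#'
#' @param followup_days Nonnegative follow-up durations in days (NA allowed).
#' @param cutoff Day cutoff (default 15); values `>= cutoff` map to 1.
#' @return Integer vector of 0/1/NA flags.
#' @export
dichotomize_followup <- function(followup_days, cutoff = 15) {
  if (any(followup_days < 0, na.rm = TRUE))
    stop("followup_days must be nonnegative")
  ifelse(is.na(followup_days), NA_integer_,
         as.integer(followup_days >= cutoff))
}
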