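## Published marginal counts of the 2011 French national SSI surveillance
## 20% sample (62280 patients, 502 wards, 151 hospitals). These margins
## calibrate the synthetic-cohort defaults and support descriptive
## cross-checks; no patient-level surveillance data are included.

#' Reference surveillance margins
#'
#' Marginal counts from the 2011 French national SSI surveillance sample
#' used to calibrate [default_config()]: total patients, SSI count, and
#' per-covariate "yes" counts overall and within the SSI / no-SSI groups
#' for the follow-up indicator.
#'
#' @return A list with `n_total`, `n_ssi`, `n_no_ssi`,
#'   `followup_lt15_no_ssi` (patients without SSI followed < 15 days) and
#'   `covariate_yes` (named total counts for the binary covariates).
#' @export
surveillance_margins <- function() {
  list(
    n_total = 62280L,
    n_ssi = 623L,
    n_no_ssi = 61657L,
    followup_lt15_no_ssi = 21371L,
    covariate_yes = c(
      gender_female = 35046L, age_ge65 = 25760L, asa_gt2 = 10818L,
      preop_ge48h = 4767L, altemeier_gt2 = 2645L, endoscopic = 10049L,
      duration_gt_p75 = 10469L, emergency = 7009L, ambulatory = 17231L,
      followup_ge15 = 40483L))
}

#' Crude SSI incidence of a cohort or of the reference margins
#'
#' @param cohort Optional `ssi_cohort`; when omitted, the reference
#'   surveillance margins are used.
#' @return Incidence as a percentage.
#' @export
crude_incidence_pct <- function(cohort = NULL) {
  if (is.null(cohort)) {
    m <- surveillance_margins()
    return(100 * m$n_ssi / m$n_total)
  }
  100 * mean(cohort$ssi)
}

#' Proportion of non-SSI patients with follow-up under 15 days
#'
#' A follow-up completeness indicator: among patients without an SSI, the
#' percentage whose post-surgery follow-up lasted less than 15 days.
#'
#' @param cohort Optional `ssi_cohort`; when omitted, the reference
#'   surveillance margins are used.
#' @return Percentage.
#' @export
short_followup_pct <- function(cohort = NULL) {
  if (is.null(cohort)) {
    m <- surveillance_margins()
    return(100 * m$followup_lt15_no_ssi / m$n_no_ssi)
  }
  sub <- cohort[cohort$ssi == 0, , drop = FALSE]
  100 * mean(sub$followup_ge15 == 0, na.rm = TRUE)
}
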