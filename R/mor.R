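## Median odds ratio: the median, over pairs of randomly chosen clusters,
## of the odds ratio between the higher- and lower-risk cluster. For a
## cluster variance sigma^2 the closed form is
##   MOR = exp(sqrt(2 sigma^2) * qnorm(0.75)),
## equal to 1 when clusters are homogeneous, and independent of outcome
## prevalence.

mor_const <- function() sqrt(2) * stats::qnorm(0.75)

#' MOR point value from a cluster variance
#'
#' @param ward_variance Cluster-level variance on the log-odds scale
#'   (scalar or vector, all >= 0).
#' @return `exp(sqrt(2 * variance) * qnorm(0.75))`; exactly 1 at variance 0.
#' @export
mor_point <- function(ward_variance) {
  if (any(ward_variance < 0)) stop("variance must be nonnegative")
  exp(sqrt(2 * ward_variance) * stats::qnorm(0.75))
}

#' Invert the MOR formula
#'
#' Returns the cluster variance implying a given MOR; used to set generator
#' variances from published MOR values.
#'
#' @param mor MOR value (>= 1).
#' @return Variance on the log-odds scale.
#' @export
mor_to_variance <- function(mor) {
  if (any(mor < 1)) stop("MOR must be >= 1")
  (log(mor) / mor_const())^2
}

#' Credibility interval for the MOR
#'
#' Applies [mor_point()] to the 2.5th and 97.5th percentiles of the
#' posterior draws of the cluster variance.
#'
#' @param variance_draws Numeric vector of at least 100 nonnegative
#'   posterior variance draws.
#' @return Named vector `c(lower, upper)`.
#' @export
mor_interval <- function(variance_draws) {
  if (length(variance_draws) < 100L) stop("need at least 100 draws")
  if (any(variance_draws < 0)) stop("variance draws must be nonnegative")
  q <- stats::quantile(variance_draws, c(0.025, 0.975), names = FALSE)
  c(lower = mor_point(q[1]), upper = mor_point(q[2]))
}

#' Effective ward variance in a slope stratum
#'
#' Under a random-coefficient model the ward effect for a patient with
#' slope-covariate value `z` is `u_0j + z * u_15j`, so the effective
#' between-ward variance is `sigma2_00` when `z = 0` and
#' `sigma2_00 + 2 sigma_01 + sigma2_11` when `z = 1`.
#'
#' @param ward_cov Numeric vector `c(sigma2_00, sigma_01, sigma2_11)` or a
#'   2x2 covariance matrix.
#' @param slope_value 0 or 1.
#' @return Effective variance (scalar).
#' @export
stratum_variance <- function(ward_cov, slope_value) {
  if (is.matrix(ward_cov))
    ward_cov <- c(ward_cov[1, 1], ward_cov[1, 2], ward_cov[2, 2])
  if (length(ward_cov) != 3L)
    stop("ward_cov must be (sigma2_00, sigma_01, sigma2_11)")
  s00 <- ward_cov[1]; s01 <- ward_cov[2]; s11 <- ward_cov[3]
  if (s00 < 0 || s11 < 0 || s01^2 > s00 * s11 + 1e-9)
    stop("ward_cov is not positive semidefinite")
  if (!slope_value %in% c(0, 1)) stop("slope_value must be 0 or 1")
  if (slope_value == 0) s00 else s00 + 2 * s01 + s11
}

#' Stratified MOR table from posterior draws
#'
#' For a random-coefficient fit, combines the ward covariance draw-wise
#' into the effective variance of each slope stratum, then reports the MOR
#' point value (formula applied to the posterior-mean variance, or to the
#' posterior median with `point = "median"`) and the percentile interval
#' ([mor_interval()]) per stratum. Fits without a random slope fall back to
#' a single `"overall"` row.
#'
#' @param fit An `ssiml_fit` (or any list with a `ward_cov` draw matrix).
#' @param point `"mean"` (default) or `"median"`: posterior functional of
#'   the variance the point MOR is computed from.
#' @return Data frame with columns `stratum`, `variance`, `mor`, `lower`,
#'   `upper`.
#' @export
stratified_mor <- function(fit, point = c("mean", "median")) {
  point <- match.arg(point)
  wc <- fit$ward_cov
  if (is.null(wc)) stop("fit has no ward-level draws")
  pt <- function(v) mor_point(if (point == "mean") mean(v)
                              else stats::median(v))
  if (ncol(wc) == 1L) {
    v <- wc[, 1L]
    ci <- mor_interval(v)
    return(data.frame(stratum = "overall",
                      variance = mean(v), mor = pt(v),
                      lower = ci["lower"], upper = ci["upper"],
                      row.names = NULL, stringsAsFactors = FALSE))
  }
  strata <- list(followup_lt15 = 0, followup_ge15 = 1)
  slope <- fit$slope_covariate
  if (!is.null(slope) && slope != "followup_ge15")
    names(strata) <- paste0(slope, c("_0", "_1"))
  out <- lapply(names(strata), function(sname) {
    z <- strata[[sname]]
    v <- apply(wc, 1L, stratum_variance, slope_value = z)
    ci <- mor_interval(v)
    data.frame(stratum = sname, variance = mean(v), mor = pt(v),
               lower = ci["lower"], upper = ci["upper"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
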