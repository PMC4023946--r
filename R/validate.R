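## Applying fitted models to held-out cohorts: predicted probabilities
## under alternative ward-effect policies, empirical-Bayes ward effects,
## standardized infection ratios, and ROC/AUC machinery with correlated
## comparison of two models scored on the same patients.

#' Predicted SSI probabilities for a cohort
#'
#' Computes `pi_ij = logistic(beta_hat . x_ij + u_0j + u_15j * z_ij)` with
#' the posterior-mean coefficients of `fit` and ward effects chosen by
#' policy:
#' * `"zero"` — all ward effects 0 (pure fixed-effect prediction; unknown
#'   wards contribute nothing);
#' * `"training"` — posterior-mean effects for wards seen in training,
#'   0 for wards unseen;
#' * `"empirical_bayes"` — effects re-estimated on the evaluation cohort
#'   itself by [estimate_ward_effects()] with the training coefficients and
#'   ward covariance held fixed.
#'
#' @param fit An `ssiml_fit`.
#' @param cohort An `ssi_cohort` carrying the fit's covariates.
#' @param ward_effect_policy One of `"empirical_bayes"`, `"training"`,
#'   `"zero"`.
#' @return Numeric vector of per-record probabilities (NA for records with
#'   missing covariates).
#' @export
predict_prob <- function(fit, cohort,
                         ward_effect_policy = c("empirical_bayes",
                                                "training", "zero")) {
  policy <- match.arg(ward_effect_policy)
  miss <- setdiff(fit$covariates, names(cohort))
  if (length(miss) > 0L)
    stop("cohort lacks fit covariate(s): ", paste(miss, collapse = ", "))
  beta <- colMeans(fit$beta)
  cc <- if (length(fit$covariates) > 0L)
    stats::complete.cases(
      as.data.frame(cohort)[, fit$covariates, drop = FALSE])
  else rep(TRUE, nrow(cohort))
  dat <- cohort[cc, , drop = FALSE]
  X <- build_design(dat, fit$covariates)
  eta <- drop(X %*% beta[colnames(X)])

  has_slope <- !is.null(fit$slope_covariate)
  if (fit$J > 0L && policy != "zero") {
    we <- if (policy == "training") fit$ward_effects
    else {
      wc <- colMeans(fit$ward_cov)
      Om <- if (has_slope)
        matrix(c(wc["sigma2_00"], wc["sigma_01"],
                 wc["sigma_01"], wc["sigma2_11"]), 2L)
      else matrix(wc["sigma2_00"])
      estimate_ward_effects(beta, Om, dat,
                            slope_covariate = fit$slope_covariate)
    }
    idx <- match(dat$ward_id, we$ward_id)
    u0 <- ifelse(is.na(idx), 0, we$u0[idx])
    eta <- eta + u0
    if (has_slope && !is.null(we$u15)) {
      u15 <- ifelse(is.na(idx), 0, we$u15[idx])
      eta <- eta + u15 * as.numeric(dat[[fit$slope_covariate]])
    }
  }
  out <- rep(NA_real_, nrow(cohort))
  out[cc] <- stats::plogis(eta)
  out
}

#' Empirical-Bayes ward effects under fixed hyperparameters
#'
#' For each ward, finds the posterior mode of its random effects given
#' fixed regression coefficients and ward covariance: a per-ward penalized
#' logistic fit with quadratic penalty `u' Omega^-1 u / 2`, solved by
#' Newton iteration. Effects shrink to zero as a ward's data vanish or the
#' covariance shrinks.
#'
#' @param beta_fixed Named coefficient vector (including `(Intercept)`)
#'   from the training fit.
#' @param ward_cov_fixed Ward covariance: a scalar/1x1 matrix (intercept
#'   only) or a 2x2 matrix (intercept + slope).
#' @param cohort An `ssi_cohort` (the evaluation data).
#' @param slope_covariate Covariate carrying the random slope (required for
#'   a 2x2 covariance; default `"followup_ge15"`).
#' @param ridge Ridge added to a (near-)singular covariance before
#'   inversion (default 1e-8).
#' @return Data frame with `ward_id`, `u0` and (for 2x2 input) `u15`.
#' @export
estimate_ward_effects <- function(beta_fixed, ward_cov_fixed, cohort,
                                  slope_covariate = "followup_ge15",
                                  ridge = 1e-8) {
  Om <- if (is.matrix(ward_cov_fixed)) ward_cov_fixed
        else matrix(ward_cov_fixed)
  q <- ncol(Om)
  if (!q %in% 1:2) stop("ward_cov_fixed must be 1x1 or 2x2")
  ev <- eigen(Om, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9) stop("ward_cov_fixed is not positive semidefinite")
  Oinv <- solve(Om + diag(ridge, q))

  covariates <- covariates_from_beta(names(beta_fixed))
  cc <- if (length(covariates) > 0L)
    stats::complete.cases(as.data.frame(cohort)[, covariates, drop = FALSE])
  else rep(TRUE, nrow(cohort))
  dat <- cohort[cc, , drop = FALSE]
  X <- build_design(dat, covariates)
  eta0 <- drop(X %*% beta_fixed[colnames(X)])
  y <- dat$ssi
  z <- if (q == 2L) as.numeric(dat[[slope_covariate]]) else NULL

  wards <- unique(dat$ward_id)
  U <- matrix(0, length(wards), q)
  ## penalized log-posterior of one ward's effects
  obj <- function(u, idx, W) {
    eta <- eta0[idx] + drop(W %*% u)
    sum(ll_point(y[idx], eta)) - 0.5 * drop(crossprod(u, Oinv %*% u))
  }
  for (jj in seq_along(wards)) {
    idx <- which(dat$ward_id == wards[jj])
    W <- if (q == 2L) cbind(1, z[idx]) else matrix(1, length(idx), 1L)
    u <- numeric(q)
    f <- obj(u, idx, W)
    for (iter in 1:100) {
      mu <- stats::plogis(eta0[idx] + drop(W %*% u))
      g <- drop(crossprod(W, y[idx] - mu)) - drop(Oinv %*% u)
      H <- crossprod(W * pmax(mu * (1 - mu), 1e-10), W) + Oinv
      step <- solve(H, g)
      ## damped Newton: halve until the penalized posterior improves
      t_ <- 1
      repeat {
        u_new <- u + t_ * step
        f_new <- obj(u_new, idx, W)
        if (f_new >= f - 1e-12 || t_ < 1e-4) break
        t_ <- t_ / 2
      }
      moved <- max(abs(u_new - u))
      u <- u_new; f <- f_new
      if (moved < 1e-9) break
    }
    U[jj, ] <- u
  }
  out <- data.frame(ward_id = wards, u0 = U[, 1L], stringsAsFactors = FALSE)
  if (q == 2L) out$u15 <- U[, 2L]
  out
}

#' Standardized infection ratio
#'
#' Observed SSI count divided by the model-expected count (a sum of
#' predicted probabilities). Values above 1 indicate more infections than
#' the case-mix predicts (lower performance).
#'
#' @param observed Nonnegative integer count of reported SSI.
#' @param expected Positive expected count.
#' @return The ratio `observed / expected`.
#' @export
sir <- function(observed, expected) {
  if (any(observed < 0) || any(observed != round(observed)))
    stop("observed must be a nonnegative integer count")
  if (any(expected <= 0))
    stop("expected count must be positive; the SIR is undefined at 0")
  observed / expected
}

#' Per-ward and overall SIR table
#'
#' @param cohort An `ssi_cohort`.
#' @param probs Per-record predicted probabilities aligned with `cohort`
#'   (NA records are excluded from both counts).
#' @return Data frame with `scope` (ward id or `"overall"`), `observed`,
#'   `expected`, `sir`.
#' @export
sir_table <- function(cohort, probs) {
  stopifnot(length(probs) == nrow(cohort))
  ok <- !is.na(probs)
  dat <- cohort[ok, , drop = FALSE]
  pr <- probs[ok]
  obs <- rowsum(dat$ssi, dat$ward_id)
  exp_ <- rowsum(pr, dat$ward_id)
  out <- data.frame(scope = rownames(obs), observed = drop(obs),
                    expected = drop(exp_), stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(scope = "overall", observed = sum(dat$ssi),
                               expected = sum(pr)))
  out$sir <- ifelse(out$expected > 0, out$observed / out$expected, NA_real_)
  rownames(out) <- NULL
  out
}

#' Area under the ROC curve (midrank estimator)
#'
#' Mann-Whitney estimator with ties contributing one half: the probability
#' that a randomly chosen case scores above a randomly chosen control.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcomes (0/1), same length.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both outcome classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve coordinates
#'
#' Sensitivity/1-specificity at every distinct score threshold. The
#' trapezoidal area under these points equals the midrank AUC.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcomes (0/1).
#' @return Data frame with `threshold`, `fpr`, `tpr`, ordered by
#'   increasing false-positive rate.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both outcome classes must be present")
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores >= t & labels == 1L) / n_pos,
                numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & labels == 0L) / n_neg,
                numeric(1))
  data.frame(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Standard error of an AUC (Hanley-McNeil)
#'
#' The 1982 formula with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`:
#' `SE = sqrt((A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)) /
#' (n_pos n_neg))`.
#'
#' @param A AUC in `[0, 1]`.
#' @param n_pos,n_neg Case and control counts (>= 1).
#' @return Standard error (>= 0).
#' @export
hanley_mcneil_se <- function(A, n_pos, n_neg) {
  stopifnot(A >= 0, A <= 1, n_pos >= 1, n_neg >= 1)
  q1 <- A / (2 - A)
  q2 <- 2 * A^2 / (1 + A)
  sqrt(max(0, A * (1 - A) + (n_pos - 1) * (q1 - A^2) +
             (n_neg - 1) * (q2 - A^2)) / (n_pos * n_neg))
}

## Placement values: for each record, the per-class placement used by the
## DeLong covariance construction.
placements <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  v10 <- vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)),
                numeric(1))
  v01 <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)),
                numeric(1))
  list(v10 = v10, v01 = v01)
}

#' Compare two correlated AUCs on the same patients
#'
#' Both score vectors must refer to the same records in the same order.
#' The default engine computes the covariance of the two AUC estimates from
#' paired placement values (the DeLong construction) and tests
#' `z = (A_a - A_b) / SE_diff`. The `"hanley_mcneil"` engine uses the 1983
#' correlated method with the intermediate correlation taken as the average
#' of the within-case and within-control Pearson correlations of the paired
#' scores (the continuous quantity the published lookup table tabulates).
#' Reported per-curve standard errors use the 1982 formula either way.
#'
#' @param scores_a,scores_b Risk scores from models A and B.
#' @param labels Binary outcomes (0/1).
#' @param engine `"delong"` (default) or `"hanley_mcneil"`.
#' @return A list of class `roc_comparison`: `auc_a`, `auc_b`, `se_a`,
#'   `se_b`, `r`, `z`, `p`, `engine`, `n_pos`, `n_neg`.
#' @export
compare_aucs <- function(scores_a, scores_b, labels,
                         engine = c("delong", "hanley_mcneil")) {
  engine <- match.arg(engine)
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels))
    stop("scores and labels must be paired (same length, same records)")
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both outcome classes must be present")
  A <- auc(scores_a, labels); B <- auc(scores_b, labels)
  se_a <- hanley_mcneil_se(A, n_pos, n_neg)
  se_b <- hanley_mcneil_se(B, n_pos, n_neg)

  if (engine == "delong") {
    pa <- placements(scores_a, labels)
    pb <- placements(scores_b, labels)
    s10 <- stats::cov(cbind(pa$v10, pb$v10))
    s01 <- stats::cov(cbind(pa$v01, pb$v01))
    Sig <- s10 / n_pos + s01 / n_neg
    var_diff <- Sig[1, 1] + Sig[2, 2] - 2 * Sig[1, 2]
    r <- if (Sig[1, 1] > 0 && Sig[2, 2] > 0)
      Sig[1, 2] / sqrt(Sig[1, 1] * Sig[2, 2]) else 0
  } else {
    r_pos <- safe_cor(scores_a[labels == 1L], scores_b[labels == 1L])
    r_neg <- safe_cor(scores_a[labels == 0L], scores_b[labels == 0L])
    r <- (r_pos + r_neg) / 2
    var_diff <- se_a^2 + se_b^2 - 2 * r * se_a * se_b
  }
  z <- if (var_diff > 0) (A - B) / sqrt(var_diff) else 0
  p <- if (var_diff > 0) 2 * stats::pnorm(-abs(z)) else 1
  structure(list(auc_a = A, auc_b = B, se_a = se_a, se_b = se_b,
                 r = r, z = z, p = p, engine = engine,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_comparison")
}

safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("AUC A = %.3f (SE %.4f), AUC B = %.3f (SE %.4f)\n",
              x$auc_a, x$se_a, x$auc_b, x$se_b))
  cat(sprintf("r = %.3f, z = %.2f, p = %.3g [%s engine]\n",
              x$r, x$z, x$p, x$engine))
  invisible(x)
}
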