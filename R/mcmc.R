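## Adaptive Metropolis-within-Gibbs sampler for 2- and 3-level Bayesian
## logistic models.
##
## Updates per iteration:
##   * fixed effects beta: one multivariate random-walk Metropolis block,
##     proposal covariance from the single-level ML fit, scale adapted
##     toward 23% acceptance during burn-in;
##   * intercept/cluster-mean translation moves (beta_0 +d, all u_0j -d;
##     likewise for the slope coefficient and u_15j, and for hospital
##     effects) that leave the likelihood invariant and decorrelate the
##     fixed effects from the cluster-effect means;
##   * ward effects u_0j (and u_15j), hospital effects v_k: simultaneous
##     per-cluster scalar random walks (the likelihood factorizes over
##     clusters given beta), common step size adapted toward 44% acceptance;
##   * variance components: conjugate Gibbs draws — inverse-gamma for scalar
##     variances, inverse-Wishart for the 2x2 ward covariance.

#' Specify a hierarchical logistic model fit
#'
#' @param covariates Character vector of covariate names (possibly empty for
#'   the empty model); `"procedure_type"` expands to five dummies against
#'   the gastrointestinal reference.
#' @param levels Random levels above the patient: `"ward"`, or
#'   `c("ward", "hospital")`, or `character(0)` for a single-level model.
#' @param random_slope Optional name of the covariate whose effect varies by
#'   ward (the random-coefficient model uses `"followup_ge15"`).
#' @param priors Overrides for the prior hyperparameters: `beta_var`
#'   (fixed-effect normal variance, default 1e6), `ig_shape`, `ig_rate`
#'   (inverse-gamma for scalar variances, default 0.001 each),
#'   `wishart_df` (default 3) and `wishart_scale` (default identity) for
#'   the inverse-Wishart on the 2x2 ward covariance.
#' @param mcmc Overrides for the chain settings: `burn_in` (default 5000),
#'   `iterations` (total, default 50000), `thin` (default 10), `seed`
#'   (default 1), `target_accept_scalar` (0.44), `target_accept_block`
#'   (0.234).
#' @return A list of class `ssiml_spec`.
#' @export
model_spec <- function(covariates = character(),
                       levels = "ward",
                       random_slope = NULL,
                       priors = list(),
                       mcmc = list()) {
  pr <- utils::modifyList(list(beta_var = 1e6, ig_shape = 0.001,
                               ig_rate = 0.001, wishart_df = 3,
                               wishart_scale = diag(2)), priors)
  mc <- utils::modifyList(list(burn_in = 5000L, iterations = 50000L,
                               thin = 10L, seed = 1L,
                               target_accept_scalar = 0.44,
                               target_accept_block = 0.234), mcmc)
  if (mc$burn_in <= 0L || mc$iterations <= mc$burn_in)
    stop("need 0 < burn_in < iterations")
  if (!all(levels %in% c("ward", "hospital")))
    stop("levels must be a subset of c('ward', 'hospital')")
  if ("hospital" %in% levels && !"ward" %in% levels)
    stop("a hospital level requires the ward level")
  if (!is.null(random_slope)) {
    if (!"ward" %in% levels)
      stop("a random slope requires the ward level")
    if (!random_slope %in% c(covariates, "followup_ge15"))
      stop("random_slope must be one of the covariates or 'followup_ge15'")
  }
  structure(list(covariates = covariates, levels = levels,
                 random_slope = random_slope, priors = pr, mcmc = mc),
            class = "ssiml_spec")
}

#' Fit a hierarchical logistic model by MCMC
#'
#' Runs the adaptive Metropolis-within-Gibbs sampler described in
#' [model_spec()] on the complete cases of `cohort` for the specified
#' covariates. Chains are reproducible from `spec$mcmc$seed`.
#'
#' @param spec An `ssiml_spec`.
#' @param cohort An `ssi_cohort`.
#' @return An object of class `ssiml_fit` holding the posterior draws
#'   (`beta`, `ward_cov`, `hospital_var`), posterior-mean ward effects,
#'   acceptance rates, and the data dimensions. Use [summary()] for the
#'   coefficient/OR table and diagnostics.
#' @export
fit_mcmc <- function(spec, cohort) {
  stopifnot(inherits(spec, "ssiml_spec"))
  used <- unique(c(spec$covariates, spec$random_slope))
  used_cols <- intersect(c(used, "procedure_type"[("procedure_type" %in% used)]),
                         names(cohort))
  cc <- if (length(used_cols) > 0L)
    stats::complete.cases(as.data.frame(cohort)[, used_cols, drop = FALSE])
  else rep(TRUE, nrow(cohort))
  dat <- cohort[cc, , drop = FALSE]
  if (nrow(dat) == 0L) stop("no complete cases for the requested covariates")

  y <- dat$ssi
  X <- build_design(dat, spec$covariates)
  p <- ncol(X)
  if (p > 1L) {
    const <- which(apply(X[, -1L, drop = FALSE], 2L,
                         function(col) stats::var(col) == 0))
    if (length(const) > 0L)
      stop("degenerate (constant) covariate column: ",
           colnames(X)[-1L][const[1]])
  }
  if (stats::var(y) == 0) stop("outcome is constant; nothing to fit")

  has_ward <- "ward" %in% spec$levels
  has_hosp <- "hospital" %in% spec$levels
  has_slope <- !is.null(spec$random_slope)
  jw <- kh <- NULL
  J <- K <- 0L
  if (has_ward) {
    wards <- unique(dat$ward_id)
    jw <- match(dat$ward_id, wards)
    J <- length(wards)
  }
  if (has_hosp) {
    hosps <- unique(dat$hospital_id)
    kh <- match(dat$hospital_id, hosps)
    K <- length(hosps)
  }
  z <- if (has_slope) as.numeric(dat[[spec$random_slope]]) else NULL
  slope_col <- if (has_slope && spec$random_slope %in% spec$covariates)
    match(spec$random_slope, colnames(X)) else NA_integer_

  ## single-level ML fit: initialization and beta proposal covariance
  ml <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  beta <- ml$coefficients
  beta[!is.finite(beta)] <- 0
  w <- ml$weights
  XtWX <- crossprod(X * sqrt(pmax(w, 1e-8)))
  Vprop <- tryCatch(chol2inv(chol(XtWX)), error = function(e) diag(p) * 0.01)
  Lprop <- tryCatch(chol(Vprop), error = function(e) diag(sqrt(diag(Vprop))))

  mc <- spec$mcmc
  pr <- spec$priors
  n_store <- (mc$iterations - mc$burn_in) %/% mc$thin

  with_seed(mc$seed, {
    u0 <- numeric(J); u15 <- numeric(J); v <- numeric(K)
    sig00 <- 0.5; sig01 <- 0; sig11 <- if (has_slope) 0.2 else 0
    Oinv <- if (has_slope) solve(matrix(c(sig00, sig01, sig01, sig11), 2))
            else NULL
    sv <- 0.1
    eta <- drop(X %*% beta)
    llcur <- ll_point(y, eta)

    ## adaptive log step sizes
    ls_beta <- log(2.38 / sqrt(p)); ls_u0 <- log(0.5); ls_u15 <- log(0.5)
    ls_v <- log(0.5); ls_t0 <- log(0.2); ls_t15 <- log(0.2); ls_tv <- log(0.2)
    acc_count <- c(beta = 0, u0 = 0, u15 = 0, v = 0)
    acc_n <- 0

    draws_beta <- matrix(NA_real_, n_store, p,
                         dimnames = list(NULL, colnames(X)))
    draws_wc <- if (has_ward)
      matrix(NA_real_, n_store,
             if (has_slope) 3L else 1L,
             dimnames = list(NULL, if (has_slope)
               c("sigma2_00", "sigma_01", "sigma2_11") else "sigma2_00"))
    draws_hv <- if (has_hosp) numeric(n_store)
    sum_u0 <- numeric(J); sum_u15 <- numeric(J); n_u <- 0L

    a_q <- function() if (has_slope) Oinv[1, 1] else 1 / sig00
    b_q <- function() if (has_slope) Oinv[1, 2] else 0
    c_q <- function() if (has_slope) Oinv[2, 2] else 0

    store_i <- 0L
    for (it in seq_len(mc$iterations)) {
      adapting <- it <= mc$burn_in
      gam <- if (adapting) min(0.05, 2 / sqrt(it)) else 0

      ## --- beta block
      delta <- exp(ls_beta) * drop(stats::rnorm(p) %*% Lprop)
      etap <- eta + drop(X %*% delta)
      llp <- ll_point(y, etap)
      betap <- beta + delta
      la <- sum(llp - llcur) -
        0.5 / pr$beta_var * (sum(betap^2) - sum(beta^2))
      apr <- min(1, exp(la))
      if (stats::runif(1) < apr) {
        beta <- betap; eta <- etap; llcur <- llp
        if (!adapting) acc_count["beta"] <- acc_count["beta"] + 1
      }
      if (adapting) ls_beta <- ls_beta + gam * (apr - mc$target_accept_block)

      ## --- translation: intercept vs ward intercepts
      if (has_ward) {
        d <- stats::rnorm(1, 0, exp(ls_t0))
        la <- -0.5 * (a_q() * (-2 * d * sum(u0) + J * d^2) +
                        2 * b_q() * (-d * sum(u15))) -
          0.5 / pr$beta_var * ((beta[1] + d)^2 - beta[1]^2)
        apr <- min(1, exp(la))
        if (stats::runif(1) < apr) { beta[1] <- beta[1] + d; u0 <- u0 - d }
        if (adapting) ls_t0 <- ls_t0 + gam * (apr - mc$target_accept_scalar)
      }
      ## --- translation: slope coefficient vs ward slopes
      if (has_slope && !is.na(slope_col)) {
        d <- stats::rnorm(1, 0, exp(ls_t15))
        la <- -0.5 * (c_q() * (-2 * d * sum(u15) + J * d^2) +
                        2 * b_q() * (-d * sum(u0))) -
          0.5 / pr$beta_var * ((beta[slope_col] + d)^2 - beta[slope_col]^2)
        apr <- min(1, exp(la))
        if (stats::runif(1) < apr) {
          beta[slope_col] <- beta[slope_col] + d; u15 <- u15 - d
        }
        if (adapting) ls_t15 <- ls_t15 + gam * (apr - mc$target_accept_scalar)
      }
      ## --- translation: intercept vs hospital effects
      if (has_hosp) {
        d <- stats::rnorm(1, 0, exp(ls_tv))
        la <- -0.5 / sv * (-2 * d * sum(v) + K * d^2) -
          0.5 / pr$beta_var * ((beta[1] + d)^2 - beta[1]^2)
        apr <- min(1, exp(la))
        if (stats::runif(1) < apr) { beta[1] <- beta[1] + d; v <- v - d }
        if (adapting) ls_tv <- ls_tv + gam * (apr - mc$target_accept_scalar)
      }

      ## --- ward intercept sweep
      if (has_ward) {
        eps <- stats::rnorm(J, 0, exp(ls_u0))
        etap <- eta + eps[jw]
        llp <- ll_point(y, etap)
        dW <- rowsum(llp - llcur, jw, reorder = FALSE)
        dpri <- -0.5 * (a_q() * (2 * u0 * eps + eps^2) +
                          2 * b_q() * eps * u15)
        la <- drop(dW) + dpri
        apr_v <- pmin(1, exp(la))
        acc <- stats::runif(J) < apr_v
        if (any(acc)) {
          u0[acc] <- u0[acc] + eps[acc]
          upd <- acc[jw]
          eta[upd] <- etap[upd]; llcur[upd] <- llp[upd]
        }
        if (adapting) ls_u0 <- ls_u0 +
            gam * (mean(apr_v) - mc$target_accept_scalar)
        else acc_count["u0"] <- acc_count["u0"] + mean(acc)
      }

      ## --- ward slope sweep
      if (has_slope) {
        eps <- stats::rnorm(J, 0, exp(ls_u15))
        etap <- eta + eps[jw] * z
        llp <- ll_point(y, etap)
        dW <- rowsum(llp - llcur, jw, reorder = FALSE)
        dpri <- -0.5 * (c_q() * (2 * u15 * eps + eps^2) +
                          2 * b_q() * eps * u0)
        la <- drop(dW) + dpri
        apr_v <- pmin(1, exp(la))
        acc <- stats::runif(J) < apr_v
        if (any(acc)) {
          u15[acc] <- u15[acc] + eps[acc]
          upd <- acc[jw]
          eta[upd] <- etap[upd]; llcur[upd] <- llp[upd]
        }
        if (adapting) ls_u15 <- ls_u15 +
            gam * (mean(apr_v) - mc$target_accept_scalar)
        else acc_count["u15"] <- acc_count["u15"] + mean(acc)
      }

      ## --- hospital sweep
      if (has_hosp) {
        eps <- stats::rnorm(K, 0, exp(ls_v))
        etap <- eta + eps[kh]
        llp <- ll_point(y, etap)
        dH <- rowsum(llp - llcur, kh, reorder = FALSE)
        dpri <- -0.5 / sv * (2 * v * eps + eps^2)
        la <- drop(dH) + dpri
        apr_v <- pmin(1, exp(la))
        acc <- stats::runif(K) < apr_v
        if (any(acc)) {
          v[acc] <- v[acc] + eps[acc]
          upd <- acc[kh]
          eta[upd] <- etap[upd]; llcur[upd] <- llp[upd]
        }
        if (adapting) ls_v <- ls_v +
            gam * (mean(apr_v) - mc$target_accept_scalar)
        else acc_count["v"] <- acc_count["v"] + mean(acc)
      }
      if (!adapting) acc_n <- acc_n + 1

      ## --- variance components (Gibbs)
      if (has_ward) {
        if (has_slope) {
          S <- pr$wishart_scale + crossprod(cbind(u0, u15))
          W <- stats::rWishart(1, df = pr$wishart_df + J, Sigma = solve(S))[, , 1]
          Oinv <- W
          Om <- solve(W)
          sig00 <- Om[1, 1]; sig01 <- Om[1, 2]; sig11 <- Om[2, 2]
        } else {
          sig00 <- 1 / stats::rgamma(1, shape = pr$ig_shape + J / 2,
                                     rate = pr$ig_rate + sum(u0^2) / 2)
        }
      }
      if (has_hosp) {
        sv <- 1 / stats::rgamma(1, shape = pr$ig_shape + K / 2,
                                rate = pr$ig_rate + sum(v^2) / 2)
      }

      ## --- storage
      if (it > mc$burn_in && (it - mc$burn_in) %% mc$thin == 0L) {
        store_i <- store_i + 1L
        draws_beta[store_i, ] <- beta
        if (has_ward) {
          draws_wc[store_i, ] <- if (has_slope) c(sig00, sig01, sig11)
                                 else sig00
        }
        if (has_hosp) draws_hv[store_i] <- sv
        if (has_ward) {
          sum_u0 <- sum_u0 + u0
          if (has_slope) sum_u15 <- sum_u15 + u15
          n_u <- n_u + 1L
        }
      }
    }

    ward_effects <- if (has_ward) {
      we <- data.frame(ward_id = wards, u0 = sum_u0 / n_u,
                       stringsAsFactors = FALSE)
      if (has_slope) we$u15 <- sum_u15 / n_u
      we
    }
    structure(list(
      beta = draws_beta,
      ward_cov = if (has_ward) draws_wc,
      hospital_var = if (has_hosp) draws_hv,
      ward_effects = ward_effects,
      spec = spec,
      covariates = spec$covariates,
      slope_covariate = spec$random_slope,
      n = nrow(dat), n_dropped = sum(!cc), J = J, K = K,
      accept = if (acc_n > 0) acc_count / acc_n else acc_count,
      ml_coef = ml$coefficients),
      class = "ssiml_fit")
  })
}

#' @export
print.ssiml_fit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical logistic fit: %d patients, %d wards%s, %d stored draws\n",
    x$n, x$J,
    if (x$K > 0) sprintf(", %d hospitals", x$K) else "",
    nrow(x$beta)))
  if (!is.null(x$slope_covariate))
    cat("random slope on:", x$slope_covariate, "\n")
  invisible(x)
}

#' Fit the empty (variance-partition) model
#'
#' No covariates; random intercepts at the requested levels (default ward
#' and hospital, the three-level variance decomposition).
#'
#' @param cohort An `ssi_cohort`.
#' @param levels Random levels (default `c("ward", "hospital")`).
#' @param mcmc,priors Overrides passed to [model_spec()].
#' @return An `ssiml_fit`.
#' @export
fit_model1_empty <- function(cohort, levels = c("ward", "hospital"),
                             mcmc = list(), priors = list()) {
  fit_mcmc(model_spec(character(), levels = levels, mcmc = mcmc,
                      priors = priors), cohort)
}

#' Fit the random-intercept model
#'
#' Patient covariates with a ward random intercept: covariate effects are
#' assumed identical across wards.
#'
#' @param cohort An `ssi_cohort`.
#' @param covariates Covariate names (default [model_covariates()]).
#' @param mcmc,priors Overrides passed to [model_spec()].
#' @return An `ssiml_fit`.
#' @export
fit_model2_intercept <- function(cohort, covariates = model_covariates(),
                                 mcmc = list(), priors = list()) {
  fit_mcmc(model_spec(covariates, levels = "ward", mcmc = mcmc,
                      priors = priors), cohort)
}

#' Fit the random-coefficient model
#'
#' As the random-intercept model, plus a ward-varying coefficient on one
#' covariate (default the follow-up >= 15 days indicator), with a full 2x2
#' covariance between the ward intercept and slope.
#'
#' @param cohort An `ssi_cohort`.
#' @param covariates Covariate names (default [model_covariates()]).
#' @param slope_covariate Covariate with the ward-varying effect.
#' @param mcmc,priors Overrides passed to [model_spec()].
#' @return An `ssiml_fit`.
#' @export
fit_model3_slope <- function(cohort, covariates = model_covariates(),
                             slope_covariate = "followup_ge15",
                             mcmc = list(), priors = list()) {
  fit_mcmc(model_spec(covariates, levels = "ward",
                      random_slope = slope_covariate, mcmc = mcmc,
                      priors = priors), cohort)
}
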