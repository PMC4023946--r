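## Posterior summaries and chain diagnostics.

#' Two-sided tail probability of a posterior sample
#'
#' `2 * min(P(theta > 0), P(theta < 0))`, floored at `2 / n_draws` so a
#' sample entirely on one side of zero reports the resolution limit rather
#' than an exact zero.
#'
#' @param draws Numeric vector of at least 100 posterior draws.
#' @return Tail probability in `[2/n, 1]`.
#' @export
coef_p <- function(draws) {
  n <- length(draws)
  if (n < 100L) stop("need at least 100 draws")
  p <- 2 * min(mean(draws > 0), mean(draws < 0))
  max(p, 2 / n)
}

## Effective sample size via Geyer's initial monotone positive sequence.
ess <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  lag_max <- min(n - 1L, 500L)
  rho <- drop(stats::acf(x, lag.max = lag_max, plot = FALSE,
                         demean = TRUE)$acf)
  ## pair sums Gamma_t = rho[2t] + rho[2t+1]; truncate at first negative,
  ## enforce monotone decrease
  m <- (length(rho) - 1L) %/% 2L
  gam <- rho[2 * seq_len(m)] + rho[2 * seq_len(m) + 1L]
  pos <- which(gam <= 0)
  if (length(pos) > 0) gam <- gam[seq_len(pos[1] - 1L)]
  gam <- cummin(gam)
  denom <- -rho[1] + 2 * (rho[1] + sum(gam))
  max(1, min(n, n / max(denom, 1e-12)))
}

## Split-chain potential scale reduction factor.
split_rhat <- function(x) {
  n <- length(x) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- cbind(x[seq_len(n)], x[seq_len(n) + n])
  mns <- colMeans(halves)
  vrs <- apply(halves, 2L, stats::var)
  W <- mean(vrs)
  B <- n * stats::var(mns)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Summarize a hierarchical logistic fit
#'
#' Coefficient table (posterior mean/SD on the log-odds scale, OR =
#' `exp(mean)`, 95% interval from the exponentiated 2.5th/97.5th draw
#' percentiles, two-sided Bayesian p from [coef_p()]), variance-component
#' table, and chain diagnostics (effective sample size and split-chain
#' scale-reduction factor). A convergence warning (any split-Rhat above
#' `rhat_warn`) is both signalled and recorded in the returned object.
#'
#' @param object An `ssiml_fit`.
#' @param rhat_warn Threshold for the convergence warning (default 1.1).
#' @param ... Unused.
#' @return A list of class `ssiml_summary` with elements `coefficients`,
#'   `variance_components`, `diagnostics`, `warnings`.
#' @export
summary.ssiml_fit <- function(object, rhat_warn = 1.1, ...) {
  B <- object$beta
  coef_tab <- data.frame(
    term = colnames(B),
    mean = colMeans(B),
    sd = apply(B, 2L, stats::sd),
    or = exp(colMeans(B)),
    or_lower = exp(apply(B, 2L, stats::quantile, 0.025)),
    or_upper = exp(apply(B, 2L, stats::quantile, 0.975)),
    p = apply(B, 2L, coef_p),
    ess = apply(B, 2L, ess),
    rhat = apply(B, 2L, split_rhat),
    row.names = NULL, stringsAsFactors = FALSE)

  vc <- NULL
  vdraws <- object$ward_cov
  if (!is.null(object$hospital_var)) {
    hv <- matrix(object$hospital_var, ncol = 1L,
                 dimnames = list(NULL, "sigma2_v"))
    vdraws <- if (is.null(vdraws)) hv else cbind(vdraws, hv)
  }
  if (!is.null(vdraws)) {
    vc <- data.frame(
      component = colnames(vdraws),
      mean = colMeans(vdraws),
      sd = apply(vdraws, 2L, stats::sd),
      lower = apply(vdraws, 2L, stats::quantile, 0.025),
      upper = apply(vdraws, 2L, stats::quantile, 0.975),
      ess = apply(vdraws, 2L, ess),
      rhat = apply(vdraws, 2L, split_rhat),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  rhats <- c(coef_tab$rhat, vc$rhat)
  warn <- character(0)
  if (any(rhats > rhat_warn, na.rm = TRUE)) {
    warn <- sprintf(
      "possible non-convergence: max split-Rhat %.3f exceeds %.2f",
      max(rhats, na.rm = TRUE), rhat_warn)
    warning(warn, call. = FALSE)
  }
  structure(list(coefficients = coef_tab, variance_components = vc,
                 diagnostics = list(accept = object$accept,
                                    n = object$n, J = object$J, K = object$K,
                                    draws = nrow(B)),
                 warnings = warn),
            class = "ssiml_summary")
}

#' @export
print.ssiml_summary <- function(x, digits = 3, ...) {
  cat("Coefficients (posterior mean, OR with 95% credibility interval):\n")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  if (!is.null(x$variance_components)) {
    cat("\nVariance components:\n")
    print(format(x$variance_components, digits = digits), row.names = FALSE)
  }
  if (length(x$warnings) > 0) cat("\nWarnings:", x$warnings, "\n")
  invisible(x)
}
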