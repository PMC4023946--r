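test_that("posterior means match ML logistic estimates with no random effects", {
  cfg <- test_config(n_hospitals = 5L, wards_per_hospital = 2L,
                     patients_per_ward = 100L, intercept = -1.5)
  co <- generate_cohort(cfg, seed = 14)
  covs <- c("asa_gt2", "duration_gt_p75", "followup_ge15")
  spec <- model_spec(covs, levels = character(0),
                     mcmc = short_mcmc(seed = 3, iterations = 6000L,
                                       burn_in = 1000L))
  fit <- fit_mcmc(spec, co)
  ml <- stats::glm(stats::reformulate(covs, "ssi"),
                   data = as.data.frame(co), family = stats::binomial())
  post_mean <- colMeans(fit$beta)
  post_sd <- apply(fit$beta, 2, stats::sd)
  expect_lt(max(abs(post_mean - stats::coef(ml)) / post_sd), 2)
})

test_that("the empty model has exactly one fixed effect and stored draw shape", {
  co <- generate_cohort(test_config(sigma00 = 0.5, seed = 4,
                                    patients_per_ward = 40L))
  fit <- fit_model1_empty(co, levels = "ward", mcmc = short_mcmc())
  expect_identical(colnames(fit$beta), "(Intercept)")
  s <- summary(fit)
  expect_equal(nrow(s$coefficients), 1L)
  expect_equal(nrow(fit$beta), (3000L - 500L) %/% 5L)
  ## every stored ward-variance draw is positive
  expect_true(all(fit$ward_cov[, "sigma2_00"] > 0))
})

test_that("random-coefficient draws satisfy the PSD constraint everywhere", {
  cfg <- test_config(n_hospitals = 15L, wards_per_hospital = 2L,
                     patients_per_ward = 60L, sigma00 = 1, sigma01 = -0.3,
                     sigma11 = 0.5, intercept = -2)
  co <- generate_cohort(cfg, seed = 21)
  fit <- fit_model3_slope(co, covariates = c("asa_gt2", "followup_ge15"),
                          mcmc = short_mcmc(seed = 2))
  wc <- fit$ward_cov
  expect_true(all(wc[, "sigma2_00"] > 0))
  expect_true(all(wc[, "sigma2_11"] >= 0))
  expect_true(all(abs(wc[, "sigma_01"]) <=
                    sqrt(wc[, "sigma2_00"] * wc[, "sigma2_11"]) + 1e-12))
  ## the generator used a nonzero slope variance; the posterior should too
  expect_gt(mean(wc[, "sigma2_11"]), 0)
})

test_that("data generated without ward variance concentrate sigma2_00 near 0", {
  cfg <- test_config(n_hospitals = 25L, wards_per_hospital = 2L,
                     patients_per_ward = 80L, sigma00 = 0, intercept = -1)
  co <- generate_cohort(cfg, seed = 31)
  fit <- fit_model1_empty(co, levels = "ward",
                          mcmc = short_mcmc(seed = 5, iterations = 6000L,
                                            burn_in = 1000L))
  lower <- stats::quantile(fit$ward_cov[, 1], 0.025)
  expect_lt(lower, 0.05)
})

test_that("chains are reproducible from the seed", {
  co <- generate_cohort(test_config(sigma00 = 0.5, seed = 4,
                                    patients_per_ward = 40L))
  f1 <- fit_model1_empty(co, levels = "ward", mcmc = short_mcmc(seed = 7))
  f2 <- fit_model1_empty(co, levels = "ward", mcmc = short_mcmc(seed = 7))
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$ward_cov, f2$ward_cov)
  f3 <- fit_model1_empty(co, levels = "ward", mcmc = short_mcmc(seed = 8))
  expect_false(identical(f1$beta, f3$beta))
})

test_that("pinning the slope variance to zero recovers the random-intercept model", {
  cfg <- test_config(n_hospitals = 20L, wards_per_hospital = 3L,
                     patients_per_ward = 50L, sigma00 = 1, intercept = -2)
  co <- generate_cohort(cfg, seed = 41)
  covs <- c("asa_gt2", "duration_gt_p75", "followup_ge15")
  m2 <- fit_model2_intercept(co, covs, mcmc = short_mcmc(seed = 1,
                                                         iterations = 6000L,
                                                         burn_in = 1000L))
  m3 <- fit_model3_slope(co, covs, mcmc = short_mcmc(seed = 1,
                                                     iterations = 6000L,
                                                     burn_in = 1000L))
  ## the data carry no slope heterogeneity, so coefficient posteriors agree
  ## within Monte-Carlo error
  mc_se <- function(fit, term) stats::sd(fit$beta[, term]) /
    sqrt(ssiml:::ess(fit$beta[, term]))
  for (term in c("asa_gt2", "duration_gt_p75")) {
    se <- sqrt(mc_se(m2, term)^2 + mc_se(m3, term)^2)
    expect_lt(abs(mean(m2$beta[, term]) - mean(m3$beta[, term])), 4 * se)
  }
})

test_that("degenerate inputs are rejected before sampling", {
  co <- generate_cohort(test_config(seed = 4))
  co$asa_gt2 <- 0L
  expect_error(fit_model2_intercept(co, c("asa_gt2"),
                                    mcmc = short_mcmc()),
               "constant")
  expect_error(model_spec(mcmc = list(burn_in = 0L)), "burn_in")
  expect_error(model_spec("asa_gt2", levels = "hospital"), "ward")
})

test_that("coef_p behaves as a two-sided tail probability with a floor", {
  set.seed(2)
  sym <- stats::rnorm(10000)
  expect_gt(coef_p(sym), 0.9)
  expect_equal(coef_p(abs(sym) + 0.001), 2 / 10000)
  shifted <- stats::rnorm(20000, 1, 1)
  expect_equal(coef_p(shifted), 2 * stats::pnorm(-1), tolerance = 0.03)
  expect_error(coef_p(stats::rnorm(50)), "at least 100")
})

test_that("doubling the chain leaves posterior means within Monte-Carlo error", {
  co <- generate_cohort(test_config(n_hospitals = 15L, sigma00 = 0.8,
                                    patients_per_ward = 50L, seed = 51,
                                    intercept = -2))
  short <- fit_model1_empty(co, levels = "ward",
                            mcmc = short_mcmc(seed = 3, iterations = 4500L,
                                              burn_in = 500L))
  long <- fit_model1_empty(co, levels = "ward",
                           mcmc = short_mcmc(seed = 3, iterations = 8500L,
                                             burn_in = 500L))
  cmp <- function(a, b) {
    se <- sqrt(stats::sd(a)^2 / ssiml:::ess(a) +
                 stats::sd(b)^2 / ssiml:::ess(b))
    expect_lt(abs(mean(a) - mean(b)), 3 * se)
  }
  cmp(short$beta[, 1], long$beta[, 1])
  cmp(short$ward_cov[, 1], long$ward_cov[, 1])
})
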