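## Independent Monte-Carlo oracle for the MOR: the median over random
## cluster pairs (u1, u2), iid N(0, sigma2), of exp(|u1 - u2|).
mor_oracle <- function(sigma2, n_pairs = 1e6, seed = 123) {
  set.seed(seed)
  u1 <- stats::rnorm(n_pairs, 0, sqrt(sigma2))
  u2 <- stats::rnorm(n_pairs, 0, sqrt(sigma2))
  stats::median(exp(abs(u1 - u2)))
}

test_that("mor_point agrees with the pairwise-sampling oracle within 1%", {
  for (s2 in c(0.25, 1, 4)) {
    expect_lt(abs(mor_point(s2) - mor_oracle(s2)) / mor_oracle(s2), 0.01)
  }
})

test_that("the published variance/MOR pairs are consistent", {
  ## variances obtained by inverting the formula reproduce the printed MORs
  expect_equal(mor_point(1.343), 3.02, tolerance = 0.002)
  expect_equal(mor_point(1.795), 3.59, tolerance = 0.002)
  expect_equal(mor_point(4.112), 6.92, tolerance = 0.002)
  expect_equal(mor_point(1.582), 3.32, tolerance = 0.002)
  expect_equal(mor_to_variance(3.02), 1.343, tolerance = 1e-3)
  ## and the oracle confirms the formula away from the fitted values
  expect_lt(abs(mor_point(1.795) - mor_oracle(1.795)) / 3.59, 0.01)
})

test_that("mor_point boundary and monotonicity", {
  expect_identical(mor_point(0), 1)
  grid <- seq(0, 5, by = 0.25)
  expect_true(all(diff(mor_point(grid)) > 0))
  expect_lt(mor_point(1e-12) - 1, 1e-5)  # continuity at zero
  expect_error(mor_point(-0.1), "nonnegative")
})

test_that("mor_interval applies the formula to the variance percentiles", {
  expect_equal(mor_interval(rep(0.7, 200)),
               c(lower = mor_point(0.7), upper = mor_point(0.7)))
  expect_equal(mor_interval(rep(0, 150)), c(lower = 1, upper = 1))
  set.seed(9)
  draws <- stats::rgamma(10000, shape = 3, rate = 2)
  direct <- mor_point(stats::quantile(draws, c(0.025, 0.975), names = FALSE))
  expect_equal(unname(mor_interval(draws)), direct)
  expect_error(mor_interval(rep(1, 50)), "at least 100")
})

test_that("stratum variance combines intercept and slope components", {
  expect_equal(stratum_variance(c(4, -1, 0.5), 1), 2.5)
  expect_equal(stratum_variance(c(1, 0, 1), 1), 2)
  expect_equal(stratum_variance(c(3, 0, 0), 0), 3)
  expect_equal(stratum_variance(c(3, 0, 0), 1), 3)  # no slope: strata equal
  expect_error(stratum_variance(c(1, 5, 1), 1), "positive semidefinite")
  expect_error(stratum_variance(c(1, 0, 1), 2), "slope_value")
  ## cross-check against the empirical variance of simulated u0 + u15
  S <- matrix(c(4, -1, -1, 0.5), 2)
  set.seed(4)
  u <- matrix(stats::rnorm(2e5), ncol = 2) %*% chol(S)
  expect_equal(stats::var(u[, 1] + u[, 2]), stratum_variance(S, 1),
               tolerance = 0.02)
})

test_that("stratified_mor reproduces the published stratum MORs from the
           matching covariance and falls back without a slope", {
  wc <- c(sigma2_00 = 4.112, sigma_01 = -1.765, sigma2_11 = 1.0)
  fit <- fake_fit(c("(Intercept)" = -3), ward_cov_means = wc,
                  slope_covariate = "followup_ge15")
  tab <- stratified_mor(fit)
  expect_identical(tab$stratum, c("followup_lt15", "followup_ge15"))
  expect_equal(tab$mor[1], 6.92, tolerance = 0.005)
  expect_equal(tab$mor[2], 3.32, tolerance = 0.005)
  ## degenerate draws give a degenerate interval
  expect_equal(tab$lower, tab$mor, tolerance = 1e-9)

  fit0 <- fake_fit(c("(Intercept)" = -3),
                   ward_cov_means = c(sigma2_00 = 0, sigma_01 = 0,
                                      sigma2_11 = 0),
                   slope_covariate = "followup_ge15")
  expect_true(all(stratified_mor(fit0)$mor == 1))

  fit2 <- fake_fit(c("(Intercept)" = -3),
                   ward_cov_means = c(sigma2_00 = 1.343))
  tab2 <- stratified_mor(fit2)
  expect_identical(tab2$stratum, "overall")
  expect_equal(tab2$mor, 3.02, tolerance = 0.002)
})

test_that("recovered MOR is invariant to outcome prevalence", {
  ## two cohorts identical except for the baseline odds
  base <- function(int, seed) generate_cohort(
    test_config(n_hospitals = 25L, wards_per_hospital = 4L,
                patients_per_ward = 50L, sigma00 = 1, intercept = int,
                beta = zero_beta()), seed = seed)
  mor_of <- function(co, seed) {
    fit <- fit_model1_empty(co, levels = "ward",
                            mcmc = short_mcmc(seed = seed,
                                              iterations = 6000L,
                                              burn_in = 1000L))
    stratified_mor(fit)$mor
  }
  m_low <- mor_of(base(-2.2, seed = 61), 1)   # rarer outcome
  m_high <- mor_of(base(-0.7, seed = 61), 1)  # common outcome
  expect_equal(m_low, m_high, tolerance = 0.2)
  ## both should sit near the generating MOR
  expect_equal(m_high, mor_point(1), tolerance = 0.25)
})
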