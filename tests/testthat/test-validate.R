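test_that("midrank AUC equals the exhaustive pairwise oracle", {
  ## brute force over all case/control pairs, ties counting one half
  auc_oracle <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  set.seed(8)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    y <- stats::rbinom(n, 1, 0.3)
    if (length(unique(y)) < 2) next
    expect_equal(auc(s, y), auc_oracle(s, y))
  }
  ## degenerate cases
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(auc(1:4, c(1, 1, 1, 1)), "both outcome classes")
})

test_that("trapezoidal area under roc_points equals the midrank AUC", {
  set.seed(3)
  s <- stats::runif(300); y <- stats::rbinom(300, 1, 0.4)
  rp <- roc_points(s, y)
  trap <- sum(diff(rp$fpr) * (utils::head(rp$tpr, -1) +
                                utils::tail(rp$tpr, -1)) / 2)
  expect_equal(trap, auc(s, y), tolerance = 1e-12)
  expect_equal(rp$fpr[1], 0)
  expect_equal(rp$tpr[nrow(rp)], 1)
})

test_that("Hanley-McNeil SE follows the closed form", {
  expect_equal(hanley_mcneil_se(1, 10, 20), 0)
  expect_equal(hanley_mcneil_se(0.5, 1, 1), 0.5)
  ## direct substitution at a generic value
  A <- 0.8; np <- 30; nn <- 200
  q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
  expect_equal(hanley_mcneil_se(A, np, nn),
               sqrt((A * (1 - A) + (np - 1) * (q1 - A^2) +
                       (nn - 1) * (q2 - A^2)) / (np * nn)))
  ## SE shrinks as cases accrue at fixed AUC
  ses <- vapply(c(10, 50, 250), hanley_mcneil_se, numeric(1), A = 0.8,
                n_neg = 100)
  expect_true(all(diff(ses) < 0))
})

test_that("paired AUC comparison: identity, antisymmetry, power", {
  set.seed(5)
  y <- stats::rbinom(2000, 1, 0.2)
  good <- y + stats::rnorm(2000, 0, 1e-3)  # essentially perfect
  noise <- stats::runif(2000)
  same <- compare_aucs(noise, noise, y)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  pow <- compare_aucs(good, noise, y)
  expect_lt(pow$p, 1e-6)
  swapped <- compare_aucs(noise, good, y)
  expect_equal(swapped$z, -pow$z, tolerance = 1e-12)
  expect_equal(swapped$p, pow$p, tolerance = 1e-12)
  expect_error(compare_aucs(noise[-1], noise, y), "paired")
  ## the 1983-style engine reports a bounded correlation and agrees on sign
  hm <- compare_aucs(good, noise, y, engine = "hanley_mcneil")
  expect_lte(abs(hm$r), 1)
  expect_lt(hm$p, 1e-4)
  expect_gt(hm$z * pow$z, 0)
})

test_that("predicted probabilities honour the ward-effect policies", {
  co <- tiny_cohort()
  b0 <- c("(Intercept)" = 0, asa_gt2 = 0)
  fit0 <- fake_fit(b0)
  expect_equal(predict_prob(fit0, co, "zero"), rep(0.5, nrow(co)))

  we <- data.frame(ward_id = c("HA.W1", "HA.W2"), u0 = c(1, -1))
  fitw <- fake_fit(c("(Intercept)" = -1, asa_gt2 = 0.5),
                   ward_effects = we)
  ## training policy: manual linear predictor for a known ward record
  p <- predict_prob(fitw, co, "training")
  expect_equal(p[1], stats::plogis(-1 + 0.5 * co$asa_gt2[1] + 1))
  expect_equal(p[5], stats::plogis(-1 + 0.5 * co$asa_gt2[5] - 1))
  ## unknown ward (HB.W1) contributes nothing under training/zero
  expect_equal(p[8], stats::plogis(-1 + 0.5 * co$asa_gt2[8]))
  expect_equal(predict_prob(fitw, co, "zero")[1],
               stats::plogis(-1 + 0.5 * co$asa_gt2[1]))
  co_missing <- co
  co_missing$asa_gt2 <- NULL
  expect_error(predict_prob(fitw, co_missing), "asa_gt2")
})

test_that("empirical-Bayes ward effects shrink and match the ML limit", {
  ## strong shrinkage: tiny prior variance pulls all effects to zero
  co <- generate_cohort(test_config(n_hospitals = 6L, sigma00 = 1,
                                    intercept = -1, seed = 17))
  beta <- c("(Intercept)" = -1)
  tiny <- estimate_ward_effects(beta, matrix(1e-10), co)
  expect_lt(max(abs(tiny$u0)), 1e-4)

  ## one large ward, diffuse prior: matches the per-ward ML intercept offset
  big <- generate_cohort(test_config(n_hospitals = 1L,
                                     wards_per_hospital = 1L,
                                     patients_per_ward = 800L,
                                     intercept = -1, seed = 18))
  loose <- estimate_ward_effects(beta, matrix(100), big)
  ml <- stats::glm(ssi ~ 1, offset = rep(-1, nrow(big)),
                   data = as.data.frame(big), family = stats::binomial())
  expect_equal(loose$u0, unname(stats::coef(ml)), tolerance = 0.02)

  ## 2x2 covariance returns a slope column and respects PSD validation
  co2 <- generate_cohort(test_config(n_hospitals = 6L, sigma00 = 1,
                                     sigma11 = 0.5, intercept = -1,
                                     seed = 19))
  eb2 <- estimate_ward_effects(beta, matrix(c(1, 0, 0, 0.5), 2), co2)
  expect_true(all(c("u0", "u15") %in% names(eb2)))
  expect_error(estimate_ward_effects(beta, matrix(c(1, 2, 2, 1), 2), co2),
               "positive semidefinite")
})

test_that("empirical-Bayes prediction beats the zero policy on heterogeneous data", {
  ## expectation over replicates of validation log-loss
  logloss <- function(p, y) -mean(y * log(p) + (1 - y) * log(1 - p))
  diffs <- vapply(1:20, function(r) {
    co <- generate_cohort(test_config(n_hospitals = 20L,
                                      wards_per_hospital = 2L,
                                      patients_per_ward = 40L,
                                      sigma00 = 1.5, intercept = -2,
                                      beta = zero_beta(), seed = 100 + r))
    beta <- c("(Intercept)" = -2)
    eb <- estimate_ward_effects(beta, matrix(1.5), co)
    idx <- match(co$ward_id, eb$ward_id)
    p_eb <- stats::plogis(-2 + eb$u0[idx])
    p_zero <- rep(stats::plogis(-2), nrow(co))
    logloss(p_zero, co$ssi) - logloss(p_eb, co$ssi)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("SIR definition, orientation, and the ML training identity", {
  expect_equal(sir(5, 5), 1)
  expect_equal(sir(0, 3.2), 0)
  expect_gt(sir(12, 6), 1)  # more observed than expected: lower performance
  expect_error(sir(3, 0), "positive")
  expect_error(sir(-1, 2), "nonnegative")
  expect_error(sir(2.5, 2), "integer")

  ## ML logistic fitted on its own training data: overall SIR is exactly 1
  co <- generate_cohort(test_config(n_hospitals = 15L, intercept = -2,
                                    seed = 23))
  ml <- stats::glm(ssi ~ asa_gt2 + duration_gt_p75 + followup_ge15,
                   data = as.data.frame(co), family = stats::binomial())
  tab <- sir_table(co, stats::fitted(ml))
  overall <- tab[tab$scope == "overall", ]
  expect_equal(sir(overall$observed, overall$expected), 1,
               tolerance = 1e-6)
  ## per-ward rows cover every ward once
  expect_setequal(setdiff(tab$scope, "overall"), unique(co$ward_id))
})
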