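test_that("score regressions recover null effects (outcome independent of scores)", {
  m <- model_implied_moments(srm_parameters())
  set.seed(51)
  R <- 120
  est <- matrix(NA_real_, R, 3)
  for (r in 1:R) {
    d <- generate_predictor_condition(150)
    d$y_T <- rnorm(150)  # outcome unrelated to the family by construction
    sc <- regression_scores(m, d)
    est[r, ] <- fsr_predictor(sc, d, "T", quiet = TRUE)$estimate[2:4]
  }
  mc_se <- apply(est, 2, sd) / sqrt(R)
  expect_true(all(abs(colMeans(est)) < 4 * mc_se))
})

test_that("regression scores as predictors give consistent coefficient estimates", {
  # with the population measurement parameters, estimates concentrate on the
  # truth as n grows
  m <- model_implied_moments(srm_parameters())
  tru <- c(0.3, 0.2, 0)
  for (n in c(500, 5000)) {
    d <- generate_predictor_condition(n, seed = 60 + n)
    fr <- fsr_predictor(regression_scores(m, d), d, "T", quiet = TRUE)
    expect_true(all(abs(fr$estimate[2:4] - tru) < 4 * fr$se_naive[2:4]))
  }
})

test_that("Bartlett scores as predictors are biased where regression scores are not", {
  m <- model_implied_moments(srm_parameters())
  set.seed(52)
  R <- 60; n <- 400
  est_b <- est_r <- matrix(NA_real_, R, 3)
  for (r in 1:R) {
    d <- generate_predictor_condition(n)
    est_b[r, ] <- fsr_predictor(bartlett_scores(m, d, "pinv"), d, "T",
                                quiet = TRUE)$estimate[2:4]
    est_r[r, ] <- fsr_predictor(regression_scores(m, d), d, "T",
                                quiet = TRUE)$estimate[2:4]
  }
  tru <- c(0.3, 0.2, 0)
  se_b <- apply(est_b, 2, sd) / sqrt(R)
  se_r <- apply(est_r, 2, sd) / sqrt(R)
  # the actor coefficient is visibly attenuated under Bartlett scoring
  expect_gt(abs(mean(est_b[, 2]) - tru[2]), 4 * se_b[2])
  expect_true(all(abs(colMeans(est_r) - tru) < 4 * se_r))
})

test_that("Bartlett scores as outcomes estimate the projected coefficients", {
  # E[beta_hat] = P Gamma: the large-n regression of every pinv Bartlett
  # score on the predictors matches the projector-transformed truth
  m <- model_implied_moments(srm_parameters())
  d <- generate_outcome_condition(20000, seed = 53)
  fr <- fsr_outcome(bartlett_scores(m, d, "pinv"), d, quiet = TRUE)
  pred <- predicted_bartlett_bias(default_outcome_gamma())
  keep <- fr$term != "(Intercept)"
  expected <- pred[cbind(match(fr$effect[keep], srm_factors()),
                         match(fr$term[keep], paste0("z_", 1:3)))]
  expect_true(all(abs(fr$estimate[keep] - expected) < 4 * fr$se_naive[keep]))
})

test_that("ANOVA scores as outcomes are unbiased on complete data", {
  set.seed(54)
  R <- 80; n <- 300
  est <- matrix(NA_real_, R, 3)
  for (r in 1:R) {
    d <- generate_outcome_condition(n)
    fr <- fsr_outcome(anova_scores(d), d, quiet = TRUE)
    est[r, ] <- fr$estimate[fr$effect == "Fam" & fr$term != "(Intercept)"]
  }
  tru <- c(0.021, -0.005, -0.094)
  mc_se <- apply(est, 2, sd) / sqrt(R)
  expect_true(all(abs(colMeans(est) - tru) < 4 * mc_se))
})

test_that("fsr input contracts: missing columns and tiny samples are refused", {
  m <- model_implied_moments(srm_parameters())
  d <- generate_predictor_condition(20, seed = 55)
  sc <- regression_scores(m, d)
  expect_error(fsr_predictor(sc, d, "Q"), "arg")
  d2 <- d[, setdiff(names(d), "y_T")]
  class(d2) <- class(d)
  expect_error(fsr_predictor(sc, d2, "T"), "y_T")
  d3 <- generate_predictor_condition(4, seed = 56)
  expect_error(fsr_predictor(regression_scores(m, d3), d3, "T", quiet = TRUE),
               "need >= 5")
})

test_that("families without scores are dropped listwise with a count", {
  m <- model_implied_moments(srm_parameters())
  d <- generate_predictor_condition(60, seed = 57)
  d$x_TM[1:10] <- NA
  sc <- anova_scores(d)
  expect_message(fr <- fsr_predictor(sc, d, "T"), "dropped 10")
  expect_equal(attr(fr, "n_used"), 50L)
  expect_equal(attr(fr, "n_dropped"), 10L)
})

test_that("the family bootstrap is reproducible and widens naive SEs for real effects", {
  g <- default_predictor_gamma()
  g$coef[, 1] <- 0.6
  g$coef[, 2] <- 0.5
  d <- generate_predictor_condition(250, gamma = g, seed = 58)
  b1 <- fsr_bootstrap(d, "regression", "srm_as_predictor", role = "T",
                      B = 120, seed = 99)
  b2 <- fsr_bootstrap(d, "regression", "srm_as_predictor", role = "T",
                      B = 120, seed = 99)
  expect_identical(b1$se_bootstrap, b2$se_bootstrap)
  # the actor-effect naive SE ignores score estimation error
  expect_gt(b1$se_bootstrap[3], b1$se_naive[3])
  expect_error(fsr_bootstrap(d, "regression", "srm_as_predictor", role = "T",
                             B = 50), "at least 100")
})
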