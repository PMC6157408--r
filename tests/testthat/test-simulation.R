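test_that("generated data reproduce the model-implied moments", {
  n <- 50000
  d <- generate_predictor_condition(n, seed = 71)
  X <- famsrm:::.dyad_matrix(d)
  Sig <- model_implied_moments(srm_parameters())$sigma
  S <- cov(X) * (n - 1) / n
  # standard error of a sample covariance entry under normality
  se <- sqrt((outer(diag(Sig), diag(Sig)) + Sig^2) / n)
  expect_true(all(abs(S - Sig) < 4 * se))
  expect_true(all(abs(diag(S) - 4) < 4 * diag(se)))
})

test_that("generators are deterministic under a seed", {
  d1 <- generate_predictor_condition(50, seed = 72)
  d2 <- generate_predictor_condition(50, seed = 72)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  o1 <- generate_outcome_condition(50, seed = 73)
  o2 <- generate_outcome_condition(50, seed = 73)
  expect_identical(as.data.frame(o1), as.data.frame(o2))
})

test_that("the latent effects in the outcome condition follow Gamma z", {
  d <- generate_outcome_condition(100000, seed = 74)
  eta <- attr(d, "latent")
  Z <- as.matrix(d[, paste0("z_", 1:3)])
  cf <- summary(lm(eta[, "Fam"] ~ Z))$coefficients[-1, ]
  tru <- default_outcome_gamma()[1, ]
  expect_true(all(abs(cf[, 1] - tru) < 4 * cf[, 2]))
  # with Gamma = 0 the latent effects are independent of z
  d0 <- generate_outcome_condition(20000, gamma = matrix(0, 9, 3), seed = 75)
  cf0 <- summary(lm(attr(d0, "latent")[, "Fam"] ~
                      as.matrix(d0[, paste0("z_", 1:3)])))$coefficients[-1, ]
  expect_true(all(abs(cf0[, 1]) < 4 * cf0[, 2]))
  expect_error(generate_outcome_condition(10, gamma = matrix(1, 9, 3)),
               "sum to zero")
})

test_that("missingness mechanisms only delete inside the eligible stratum", {
  d <- generate_predictor_condition(2000, seed = 76)
  expect_identical(apply_missingness(d, "none"), d)
  dm <- apply_missingness(d, "pred_dyad", seed = 77)
  q1 <- quantile(d$x_TS, 0.25, names = FALSE)
  safe <- d$x_TS >= q1
  expect_false(anyNA(dm$x_TM[safe]))
  expect_false(anyNA(dm$x_TF[safe]))
  # only the two designated dyads are ever deleted
  other <- setdiff(paste0("x_", srm_dyads()), c("x_TM", "x_TF"))
  expect_false(anyNA(as.matrix(dm[, other])))
  expect_error(apply_missingness(d, "out_of_scope"), "arg")
})

test_that("family-level missing rates match their closed forms", {
  # P(>=1 missing) = 0.40-stratum share x (1 - (1-rate)^k)
  d <- generate_outcome_condition(10000, seed = 78)
  r_out <- family_missing_rate(apply_missingness(d, "out_dyad", seed = 79))
  expect_lt(abs(r_out - 0.25 * (1 - 0.6^6)), 3 * sqrt(0.238 * 0.762 / 10000))
  d2 <- generate_predictor_condition(10000, seed = 80)
  r_pred <- family_missing_rate(apply_missingness(d2, "pred_outcome", seed = 81))
  expect_lt(abs(r_pred - 0.25 * (1 - 0.75^3)), 3 * sqrt(0.145 * 0.855 / 10000))
})

test_that("summarize_replicates matches hand-computed values", {
  e <- cbind(b = c(1.0, 1.2, 0.8, 1.1, 0.9))
  s <- cbind(b = rep(0.2, 5))
  out <- summarize_replicates(e, s, c(b = 1), min_reps = 5)
  expect_equal(out$median_est, 1.0)
  expect_equal(out$bias_z, 0)
  expect_equal(out$coverage, 1)
  expect_equal(out$mad, 0.1)
  expect_equal(out$n_converged, 5L)
  # all estimates equal to truth: z = 0, MAD = 0, coverage 1
  out0 <- summarize_replicates(cbind(b = rep(1, 5)), s, c(b = 1), min_reps = 5)
  expect_equal(out0$bias_z, 0)
  expect_equal(out0$mad, 0)
  expect_equal(out0$coverage, 1)
  # hand-checked nonzero bias z: (median - truth) / (1.2533 sd / sqrt(R))
  out2 <- summarize_replicates(e, s, c(b = 0.9), min_reps = 5)
  expect_equal(out2$bias_z, 0.1 / (1.2533 * sd(e) / sqrt(5)), tolerance = 1e-12)
  # MAD is shift invariant
  out3 <- summarize_replicates(e + 5, s, c(b = 6), min_reps = 5)
  expect_equal(out3$mad, out$mad)
  # under-populated cells are flagged, not summarized
  out4 <- summarize_replicates(e, s, c(b = 1), min_reps = 10)
  expect_true(is.na(out4$median_est))
  expect_equal(out4$n_converged, 5L)
})

test_that("run_study is reproducible and reports convergence and missingness", {
  cfg <- srm_sim_config("srm_as_predictor", n_families = 120, reps = 5,
                        seed = 82, missing = "pred_dyad",
                        methods = c("regression_fiml", "anova"))
  s1 <- run_study(cfg, min_reps = 5)
  s2 <- run_study(cfg, min_reps = 5)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_true(all(s1$convergence_rate >= 0 & s1$convergence_rate <= 1))
  expect_true(all(s1$missing_rate > 0))
  expect_equal(nrow(s1), 2 * 12)
  # estimates exist for converged cells
  expect_true(all(is.finite(s1$median_est[s1$n_converged == 5])))
})

test_that("simulation configs can be read from YAML", {
  skip_if_not_installed("yaml")
  path <- tempfile(fileext = ".yaml")
  writeLines(c("condition: srm_as_predictor", "n_families: 80", "reps: 3",
               "seed: 5", "missing: pred_dyad",
               "methods: [regression_fiml, anova]"), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "srm_sim_config")
  expect_equal(cfg$n_families, 80L)
  expect_equal(cfg$methods, c("regression_fiml", "anova"))
})
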