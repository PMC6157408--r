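test_that("scores are zero when the data sit at the model mean", {
  p <- rich_params()
  m <- model_implied_moments(p)
  X <- matrix(m$mean_vector, 3, 12, byrow = TRUE)
  d <- srm_data(X)
  for (sc in list(regression_scores(m, d),
                  regression_fiml_scores(m, d),
                  bartlett_scores(m, d, "pinv"),
                  bartlett_fiml_scores(m, d))) {
    expect_lt(max(abs(unclass(sc))), 1e-10)
  }
})

test_that("the Sigma-based and Theta-based regression weightings agree", {
  set.seed(42)
  for (i in 1:5) {
    p <- random_params()
    m <- model_implied_moments(p)
    X <- matrix(rnorm(10 * 12), 10, 12)
    sc <- regression_scores(m, srm_data(X))
    # independent construction: (Psi^-1 + L' Th^-1 L)^-1 L' Th^-1
    Thi <- solve(m$resid_cov)
    FSC8 <- solve(solve(m$factor_cov) + t(m$loading) %*% Thi %*% m$loading) %*%
      t(m$loading) %*% Thi
    sc8 <- sweep(X, 2, m$mean_vector) %*% t(FSC8)
    expect_lt(max(abs(unclass(sc) - sc8)), 1e-8)
  }
})

test_that("single-factor toy model reproduces the closed-form shrinkage score", {
  psi <- 0.8; th <- 0.5
  m <- toy_model(3, psi, th, mu = rep(2, 3))
  set.seed(1)
  X <- matrix(rnorm(20 * 3, mean = 2), 20, 3)
  sc <- regression_scores(m, X)
  shrink <- (3 * psi / (3 * psi + th)) * rowMeans(X - 2)
  expect_equal(unname(unclass(sc)[, 1]), shrink, tolerance = 1e-10)
})

test_that("FIML regression scores reduce to complete-data scores without missingness", {
  set.seed(2)
  m <- model_implied_moments(rich_params())
  d <- generate_predictor_condition(40, rich_params(), seed = 3)
  s1 <- regression_scores(m, d)
  s2 <- regression_fiml_scores(m, d)
  expect_lt(max(abs(unclass(s1) - unclass(s2))), 1e-12)
})

test_that("a family with all indicators missing is shrunk to the factor mean", {
  m <- model_implied_moments(rich_params())
  X <- rbind(m$mean_vector + 1, rep(NA_real_, 12))
  expect_warning(sc <- regression_fiml_scores(m, srm_data(X)),
                 "no observed indicators")
  expect_equal(unname(unclass(sc)[2, ]), rep(0, 9))
  # Bartlett has no prior to shrink to: missing scores instead
  sb <- bartlett_fiml_scores(m, srm_data(X))
  expect_true(all(is.na(unclass(sb)[2, ])))
  expect_false(anyNA(unclass(sb)[1, ]))
})

test_that("FIML regression scores are centered under MAR deletion", {
  m <- model_implied_moments(srm_parameters())
  d <- generate_predictor_condition(5000, seed = 17)
  d <- apply_missingness(d, "pred_dyad", seed = 18)
  sc <- unclass(regression_fiml_scores(m, d))
  se <- apply(sc, 2, sd) / sqrt(nrow(sc))
  expect_true(all(abs(colMeans(sc)) < 4 * se))
})

test_that("full-rank Bartlett variants agree and the SRM variants fail with a rank error", {
  m <- toy_model(4, 0.9, 0.3)
  set.seed(3)
  X <- matrix(rnorm(15 * 4), 15, 4)
  s_res <- bartlett_scores(m, X, "residual")
  s_gls <- bartlett_scores(m, X, "gls")
  expect_lt(max(abs(unclass(s_res) - unclass(s_gls))), 1e-8)
  # SRM loading matrix: the 9 x 9 system has rank 7 -> explicit failure
  msrm <- model_implied_moments(srm_parameters())
  d <- srm_data(matrix(rnorm(24), 2, 12))
  expect_error(bartlett_scores(msrm, d, "residual"), "rank 7 < 9")
  expect_error(bartlett_scores(msrm, d, "gls"), "rank 7 < 9")
  expect_silent(bartlett_scores(msrm, d, "pinv"))
})

test_that("Bartlett pinv score coefficients compose to the rank-7 projector", {
  m <- model_implied_moments(srm_parameters())
  sc <- bartlett_scores(m, srm_data(matrix(rnorm(24), 2, 12)), "pinv")
  FSC <- attr(sc, "fsc")$complete
  P <- bartlett_projection_matrix()$projector
  expect_equal(round(FSC %*% m$loading, 3), round(P, 3), ignore_attr = TRUE)
})

test_that("Bartlett FIML equals the pinv variant on complete data and tracks rank", {
  m <- model_implied_moments(rich_params())
  d <- generate_predictor_condition(30, rich_params(), seed = 4)
  s1 <- bartlett_scores(m, d, "pinv")
  s2 <- bartlett_fiml_scores(m, d)
  expect_lt(max(abs(unclass(s1) - unclass(s2))), 1e-12)
  expect_equal(unname(attr(s2, "effective_rank")), 7)
})

test_that("deleting indicators never raises the Bartlett score-system rank", {
  m <- model_implied_moments(srm_parameters())
  Thi <- solve(m$resid_cov)
  rank_of <- function(idx) {
    Lo <- m$loading[idx, , drop = FALSE]
    famsrm:::.mat_rank(t(Lo) %*% solve(m$resid_cov[idx, idx, drop = FALSE]) %*% Lo)
  }
  set.seed(7)
  for (i in 1:60) {
    k <- sample(2:12, 1)
    idx <- sort(sample(12, k))
    r_full <- rank_of(idx)
    expect_lte(r_full, 7L)
    # drop one more indicator: rank can only stay or decrease
    idx2 <- idx[-sample(length(idx), 1)]
    if (length(idx2)) expect_lte(rank_of(idx2), r_full)
  }
})

test_that("ANOVA scores match the weighted row/column-mean formulas", {
  # constant table: family score c, all actor/partner scores 0
  Xc <- matrix(5, 2, 12)
  sc <- unclass(anova_scores(Xc))
  expect_equal(unname(sc[1, 1]), 5)
  expect_lt(max(abs(sc[, 2:9])), 1e-12)
  # hand-computed single-cell example: grand 2/3, actor_M = 2
  s8 <- unclass(anova_scores(matrix(one_cell_table(8), 1, 12)))
  expect_equal(unname(s8[1, "Fam"]), 2 / 3)
  expect_equal(unname(s8[1, "Act_M"]), 2)
  # zero-sum identities on random tables
  set.seed(9)
  X <- matrix(rnorm(50 * 12), 50, 12)
  s <- unclass(anova_scores(X))
  expect_lt(max(abs(rowSums(s[, 2:5]))), 1e-12)
  expect_lt(max(abs(rowSums(s[, 6:9]))), 1e-12)
  # family score is the family's own mean decomposition
  expect_equal(s[, "Fam"], rowMeans(X))
  # any missing dyad: all nine scores missing
  X[3, 7] <- NA
  s2 <- unclass(anova_scores(X))
  expect_true(all(is.na(s2[3, ])))
  expect_false(anyNA(s2[-3, ]))
})

test_that("scores equal the stored score coefficients applied to the data", {
  m <- model_implied_moments(rich_params())
  d <- generate_predictor_condition(25, rich_params(), seed = 6)
  d <- apply_missingness(d, "pred_dyad", seed = 7)
  X <- famsrm:::.dyad_matrix(d)
  for (sc in list(suppressWarnings(regression_fiml_scores(m, d)),
                  bartlett_fiml_scores(m, d))) {
    fsc <- attr(sc, "fsc")
    obs <- !is.na(X)
    key <- apply(obs, 1, paste0, collapse = "")
    for (i in seq_len(nrow(X))) {
      k <- key[i]
      if (is.null(fsc[[k]])) next
      idx <- which(obs[i, ])
      expect_equal(unclass(sc)[i, ],
                   drop(fsc[[k]] %*% (X[i, idx] - m$mean_vector[idx])),
                   tolerance = 1e-10)
    }
  }
  # ANOVA coefficients act on the raw (uncentered) table
  sa <- anova_scores(d)
  cc <- complete.cases(X)
  expect_equal(unclass(sa)[cc, ],
               X[cc, ] %*% t(attr(sa, "fsc")$complete),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("Bartlett scores are conditionally projected, regression scores shrunk", {
  # E[eta_hat | eta] = P eta for pinv Bartlett: multivariate regression of
  # scores on the true latent draws recovers the projector columns
  m <- model_implied_moments(srm_parameters())
  d <- generate_predictor_condition(20000, seed = 101)
  eta <- attr(d, "latent")
  sb <- unclass(bartlett_scores(m, d, "pinv"))
  P <- bartlett_projection_matrix()$projector
  for (f in c(1L, 2L, 6L)) {
    fit <- lm(sb[, f] ~ eta)
    cf <- summary(fit)$coefficients[-1, ]
    expect_true(all(abs(cf[, 1] - P[, f]) < 4 * cf[, 2]))
  }
  # regression scores are conditionally biased toward zero: the slope of
  # the family score on the family effect is strictly below its projector
  # counterpart
  sr <- unclass(regression_scores(m, d))
  slope <- coef(lm(sr[, 1] ~ eta[, 1]))[2]
  expect_lt(slope, P[1, 1])
})
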