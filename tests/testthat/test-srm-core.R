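test_that("loading matrix has the SRM structure", {
  L <- srm_loading_matrix()
  expect_equal(dim(L), c(12L, 9L))
  expect_true(all(L %in% c(0, 1)))
  # row for dyad (i, j): ones exactly at family, actor i, partner j
  expect_equal(unname(L["MF", ]),
               c(1, 1, 0, 0, 0, 0, 1, 0, 0))
  expect_equal(unname(L["ST", ]),
               c(1, 0, 0, 0, 1, 0, 0, 1, 0))
  expect_equal(unname(rowSums(L)), rep(3, 12))
  expect_equal(unname(L[, "Fam"]), rep(1, 12))
})

test_that("loading matrix has rank 7 with the known two-dimensional null space", {
  L <- srm_loading_matrix()
  # svd as an independent rank oracle
  d <- svd(L)$d
  expect_equal(sum(d > 1e-10 * d[1]), 7L)
  n1 <- c(-1, 1, 1, 1, 1, 0, 0, 0, 0)   # family = sum of actor columns
  n2 <- c(-1, 0, 0, 0, 0, 1, 1, 1, 1)   # family = sum of partner columns
  expect_lt(max(abs(L %*% n1)), 1e-12)
  expect_lt(max(abs(L %*% n2)), 1e-12)
})

test_that("model-implied moments match the variance decomposition identities", {
  m <- model_implied_moments(srm_parameters())
  # Var(X_ij) = fam + actor + partner + relationship = 1 + 1 + 0.5 + 1.5
  expect_equal(unname(diag(m$sigma)), rep(4, 12))
  # Cov(X_MF, X_FM) = fam + gen_M + gen_F + dyad_M/F
  p <- srm_parameters()
  expect_equal(m$sigma["MF", "FM"],
               p$fam_var + p$gen_recip["M"] + p$gen_recip["F"] +
                 p$dyad_recip["M/F"],
               ignore_attr = TRUE)
  # entrywise check against the quadratic form for a random parameter set
  set.seed(11)
  pr <- random_params()
  mr <- model_implied_moments(pr)
  brute <- mr$loading %*% famsrm:::.psi_matrix(pr) %*% t(mr$loading) +
    famsrm:::.theta_matrix(pr)
  expect_equal(mr$sigma, brute, ignore_attr = TRUE)
})

test_that("all covariances zero with unit variances gives Lambda Lambda' plus diagonal", {
  p <- srm_parameters(fam_var = 1, act_var = 1, par_var = 1, gen_recip = 0,
                      resid_var = 1, dyad_recip = 0)
  m <- model_implied_moments(p)
  L <- srm_loading_matrix()
  expect_equal(m$sigma, L %*% t(L) + diag(12), ignore_attr = TRUE)
})

test_that("supplied Psi/Theta matrices are rejected when they violate the SRM pattern", {
  p <- srm_parameters()
  Psi_bad <- famsrm:::.psi_matrix(p)
  Psi_bad[1, 2] <- Psi_bad[2, 1] <- 0.3   # family-actor covariance is not allowed
  expect_error(model_implied_moments(p, factor_cov = Psi_bad), "pattern")
  Theta_bad <- famsrm:::.theta_matrix(p)
  Theta_bad[1, 2] <- Theta_bad[2, 1] <- 0.3  # MF-MT is not a reciprocal pair
  expect_error(model_implied_moments(p, resid_cov = Theta_bad), "pattern")
})

test_that("variance decomposition returns shares that sum to one", {
  vd <- variance_decomposition(srm_parameters())
  expect_equal(vd$family, rep(0.25, 12))
  expect_equal(vd$actor, rep(0.25, 12))
  expect_equal(vd$partner, rep(0.125, 12))
  expect_equal(vd$relationship, rep(0.375, 12))
  vd0 <- variance_decomposition(srm_parameters(fam_var = 0))
  expect_equal(vd0$family, rep(0, 12))
  set.seed(21)
  for (i in 1:5) {
    v <- variance_decomposition(random_params())
    expect_lt(max(abs(rowSums(v[, -1]) - 1)), 1e-12)
  }
  expect_error(variance_decomposition(srm_parameters(fam_var = -1)),
               "nonnegative")
})

test_that("mean decomposition is exact, constrained, and unique", {
  # constant vector: everything in the family mean
  d <- srm_means_from_observed(rep(3.2, 12))
  expect_equal(d$mean_fam, 3.2)
  expect_equal(unname(d$mean_act), rep(0, 4))
  expect_equal(unname(d$mean_par), rep(0, 4))
  expect_equal(unname(d$mean_rel), rep(0, 12))
  # hand-computed example: single cell X_MF = 8
  d8 <- srm_means_from_observed(one_cell_table(8))
  expect_equal(d8$mean_fam, 2 / 3)
  expect_equal(unname(d8$mean_act["M"]), 2)
  # random vectors: the decomposition satisfies all zero-sum constraints and
  # recomposes exactly; with the constraints this characterizes it uniquely
  set.seed(5)
  dy <- srm_dyads()
  for (i in 1:20) {
    mu <- rnorm(12, sd = 3)
    dd <- srm_means_from_observed(mu)
    expect_equal(dd$mean_fam, mean(mu))
    expect_lt(abs(sum(dd$mean_act)), 1e-12)
    expect_lt(abs(sum(dd$mean_par)), 1e-12)
    for (r in srm_roles()) {
      expect_lt(abs(sum(dd$mean_rel[substr(dy, 1, 1) == r])), 1e-12)
      expect_lt(abs(sum(dd$mean_rel[substr(dy, 2, 2) == r])), 1e-12)
    }
    rec <- dd$mean_fam + dd$mean_act[substr(dy, 1, 1)] +
      dd$mean_par[substr(dy, 2, 2)] + dd$mean_rel
    expect_lt(max(abs(rec - mu)), 1e-12)
  }
})

test_that("mean decomposition round-trips through the model-implied mean vector", {
  p <- rich_params()
  mu <- model_implied_moments(p)$mean_vector
  d <- srm_means_from_observed(mu)
  expect_equal(d$mean_fam, p$mean_fam)
  expect_equal(d$mean_act, p$mean_act)
  expect_equal(d$mean_par, p$mean_par)
  expect_equal(d$mean_rel, p$mean_rel, tolerance = 1e-12)
})

test_that("parameter constructors enforce the mean constraints", {
  expect_error(srm_parameters(mean_act = c(1, 0, 0, 0)), "sum to zero")
  expect_error(srm_parameters(mean_rel = c(1, rep(0, 11))), "sum to zero")
  expect_silent(srm_parameters(mean_act = c(1, -1, 0.5, -0.5)))
})

test_that("free-parameter bookkeeping: 13 + 18 + 12 = 43", {
  expect_length(famsrm:::.cov_par_names(), 31L)
  # plus the 12 saturated means carried alongside in every fit
  expect_length(true_theta(srm_parameters()), 31L)
})
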