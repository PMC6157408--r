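# Internal multivariate-normal pattern-likelihood engine.
#
# All fits minimize the deviance (-2 log-likelihood) of the observed-data
# pattern likelihood with analytic gradients.  The covariance-structure
# parameter block is shared by all model types:
#   theta[1]      family variance
#   theta[2:5]    actor variances (M, F, T, S)
#   theta[6:9]    partner variances
#   theta[10:13]  generalized reciprocities
#   theta[14:25]  relationship(+error) variances per dyad
#   theta[26:31]  dyadic reciprocities per unordered pair
# Variances are optimized unconstrained so Heywood-type solutions can occur
# and be flagged via the positive-definiteness check instead of being
# silenced by a transform.

.N_COV <- 31L

.cov_par_names <- function() {
  c("fam_var", paste0("act_var_", srm_roles()), paste0("par_var_", srm_roles()),
    paste0("gen_recip_", srm_roles()), paste0("resid_var_", srm_dyads()),
    paste0("dyad_recip_", gsub("/", "_", srm_dyad_pairs(), fixed = TRUE)))
}

.cov_from_theta <- function(tc) {
  Psi <- diag(tc[1:9])
  gi <- cbind(2:5, 6:9)
  Psi[gi] <- tc[10:13]
  Psi[gi[, 2:1]] <- tc[10:13]
  Theta <- diag(tc[14:25])
  pi <- .pair_index()
  Theta[pi] <- tc[26:31]
  Theta[pi[, 2:1]] <- tc[26:31]
  list(Psi = Psi, Theta = Theta)
}

.theta_from_params <- function(p) {
  stats::setNames(c(p$fam_var, p$act_var, p$par_var, p$gen_recip,
                    p$resid_var, p$dyad_recip), .cov_par_names())
}

# gradient of the deviance wrt the 13 Psi parameters, from H = L' G L
.psi_grad <- function(H) {
  c(H[1L, 1L], diag(H)[2:5], diag(H)[6:9], 2 * H[cbind(2:5, 6:9)])
}

# gradient wrt the 18 Theta parameters, from the dyad block of G
.theta_grad <- function(G12) {
  pi <- .pair_index()
  c(diag(G12), 2 * G12[pi])
}

# group rows of X by missingness pattern; sufficient statistics per pattern
.pattern_stats <- function(X) {
  obs <- !is.na(X)
  keep <- rowSums(obs) > 0L
  dropped <- sum(!keep)
  X <- X[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  key <- apply(obs, 1L, paste0, collapse = "")
  pats <- lapply(split(seq_len(nrow(X)), key), function(rows) {
    idx <- which(obs[rows[1L], ])
    Xp <- X[rows, idx, drop = FALSE]
    xbar <- colMeans(Xp)
    list(idx = idx, n = length(rows), k = length(idx), xbar = xbar,
         S = crossprod(sweep(Xp, 2L, xbar)) / length(rows))
  })
  list(pats = unname(pats), n = nrow(X), dropped = dropped,
       census = sort(table(key), decreasing = TRUE))
}

# raw per-pattern storage (needed when means vary by family, MIMIC case)
.pattern_raw <- function(X, Z) {
  obs <- !is.na(X)
  keep <- rowSums(obs) > 0L
  dropped <- sum(!keep)
  X <- X[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  Z <- Z[keep, , drop = FALSE]
  key <- apply(obs, 1L, paste0, collapse = "")
  pats <- lapply(split(seq_len(nrow(X)), key), function(rows) {
    idx <- which(obs[rows[1L], ])
    list(idx = idx, n = length(rows), k = length(idx),
         X = X[rows, idx, drop = FALSE], Z = Z[rows, , drop = FALSE])
  })
  list(pats = unname(pats), n = nrow(X), dropped = dropped,
       census = sort(table(key), decreasing = TRUE))
}

.BIG_DEV <- 1e10

# --- measurement-only model (12 indicators, saturated global mean) ----------

# theta = c(31 covariance parameters, 12 dyad means)
.meas_eval <- function(theta, P, Lam) {
  ct <- .cov_from_theta(theta[1:31])
  mu <- theta[32:43]
  Sigma <- Lam %*% ct$Psi %*% t(Lam) + ct$Theta
  dev <- 0
  G <- matrix(0, 12L, 12L)
  gmu <- numeric(12L)
  for (p in P$pats) {
    So <- Sigma[p$idx, p$idx, drop = FALSE]
    ch <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(ch)) return(list(dev = .BIG_DEV, grad = numeric(43L), ok = FALSE))
    Si <- chol2inv(ch)
    d <- p$xbar - mu[p$idx]
    W <- p$S + tcrossprod(d)
    dev <- dev + p$n * (2 * sum(log(diag(ch))) + sum(Si * W) + p$k * log(2 * pi))
    Gp <- p$n * (Si - Si %*% W %*% Si)
    G[p$idx, p$idx] <- G[p$idx, p$idx] + Gp
    gmu[p$idx] <- gmu[p$idx] - 2 * p$n * drop(Si %*% d)
  }
  H <- crossprod(Lam, G %*% Lam)
  list(dev = dev, grad = c(.psi_grad(H), .theta_grad(G), gmu), ok = TRUE)
}

# --- joint SRM + role-specific outcomes (predictor direction) ---------------

# theta = c(31 cov, per-role slopes b_fam/b_act/b_par (3m), outcome residual
#           variances (m), 12 dyad means, outcome intercepts (m))
.joint_eval <- function(theta, P, Lam, role_idx) {
  m <- length(role_idx)
  nv <- 12L + m
  tc <- theta[1:31]
  sl <- matrix(theta[31L + seq_len(3L * m)], nrow = m, byrow = TRUE)  # fam, act, par
  vy <- theta[31L + 3L * m + seq_len(m)]
  mu <- c(theta[31L + 4L * m + 1:12], theta[31L + 4L * m + 12L + seq_len(m)])
  ct <- .cov_from_theta(tc)
  B <- matrix(0, m, 9L)
  B[cbind(seq_len(m), 1L)] <- sl[, 1L]
  B[cbind(seq_len(m), 1L + role_idx)] <- sl[, 2L]
  B[cbind(seq_len(m), 5L + role_idx)] <- sl[, 3L]
  L <- rbind(Lam, B)
  Tm <- matrix(0, nv, nv)
  Tm[1:12, 1:12] <- ct$Theta
  diag(Tm)[12L + seq_len(m)] <- vy
  Sigma <- L %*% ct$Psi %*% t(L) + Tm
  dev <- 0
  G <- matrix(0, nv, nv)
  gmu <- numeric(nv)
  for (p in P$pats) {
    So <- Sigma[p$idx, p$idx, drop = FALSE]
    ch <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(ch)) return(list(dev = .BIG_DEV, grad = numeric(length(theta)), ok = FALSE))
    Si <- chol2inv(ch)
    d <- p$xbar - mu[p$idx]
    W <- p$S + tcrossprod(d)
    dev <- dev + p$n * (2 * sum(log(diag(ch))) + sum(Si * W) + p$k * log(2 * pi))
    Gp <- p$n * (Si - Si %*% W %*% Si)
    G[p$idx, p$idx] <- G[p$idx, p$idx] + Gp
    gmu[p$idx] <- gmu[p$idx] - 2 * p$n * drop(Si %*% d)
  }
  H <- crossprod(L, G %*% L)
  GLP <- G %*% L %*% ct$Psi
  gsl <- numeric(3L * m)
  for (r in seq_len(m)) {
    gsl[3L * (r - 1L) + 1:3] <- 2 * GLP[12L + r, c(1L, 1L + role_idx[r], 5L + role_idx[r])]
  }
  grad <- c(.psi_grad(H), .theta_grad(G[1:12, 1:12]), gsl,
            diag(G)[12L + seq_len(m)], gmu[1:12], gmu[12L + seq_len(m)])
  list(dev = dev, grad = grad, ok = TRUE)
}

# --- MIMIC model: SRM effects regressed on fixed predictors -----------------

# Gamma (9 x K) from its free parameters: family row free, actor rows M,F,T
# free with S = -(M+F+T), partner rows likewise.
.gamma_from_free <- function(v, K) {
  Gam <- matrix(0, 9L, K, dimnames = list(srm_factors(), NULL))
  Gam[1L, ] <- v[seq_len(K)]
  Gam[2:4, ] <- matrix(v[K + seq_len(3 * K)], 3L, K, byrow = TRUE)
  Gam[5L, ] <- -colSums(Gam[2:4, , drop = FALSE])
  Gam[6:8, ] <- matrix(v[4 * K + seq_len(3 * K)], 3L, K, byrow = TRUE)
  Gam[9L, ] <- -colSums(Gam[6:8, , drop = FALSE])
  Gam
}

# chain full 9 x K Gamma gradient to the 7K free parameters
.gamma_grad_free <- function(gGam, K) {
  c(gGam[1L, ],
    t(gGam[2:4, , drop = FALSE] - matrix(gGam[5L, ], 3L, K, byrow = TRUE)),
    t(gGam[6:8, , drop = FALSE] - matrix(gGam[9L, ], 3L, K, byrow = TRUE)))
}

# theta = c(31 cov, 12 dyad means, 7K free structural coefficients)
.mimic_eval <- function(theta, P, Lam, K) {
  ct <- .cov_from_theta(theta[1:31])
  mu <- theta[32:43]
  Gam <- .gamma_from_free(theta[43L + seq_len(7L * K)], K)
  Sigma <- Lam %*% ct$Psi %*% t(Lam) + ct$Theta
  M <- Lam %*% Gam   # 12 x K conditional-mean slopes
  dev <- 0
  G <- matrix(0, 12L, 12L)
  gmu <- numeric(12L)
  gM <- matrix(0, 12L, K)
  for (p in P$pats) {
    So <- Sigma[p$idx, p$idx, drop = FALSE]
    ch <- tryCatch(chol(So), error = function(e) NULL)
    if (is.null(ch)) return(list(dev = .BIG_DEV, grad = numeric(length(theta)), ok = FALSE))
    Si <- chol2inv(ch)
    Mu <- matrix(mu[p$idx], p$n, p$k, byrow = TRUE) +
      p$Z %*% t(M[p$idx, , drop = FALSE])
    R <- p$X - Mu
    RS <- R %*% Si
    dev <- dev + p$n * (2 * sum(log(diag(ch))) + p$k * log(2 * pi)) + sum(RS * R)
    W <- crossprod(R)
    G[p$idx, p$idx] <- G[p$idx, p$idx] + p$n * Si - Si %*% W %*% Si
    gmu[p$idx] <- gmu[p$idx] - 2 * colSums(RS)
    gM[p$idx, ] <- gM[p$idx, ] - 2 * crossprod(RS, p$Z)
  }
  H <- crossprod(Lam, G %*% Lam)
  gGam <- crossprod(Lam, gM)
  list(dev = dev,
       grad = c(.psi_grad(H), .theta_grad(G), gmu, .gamma_grad_free(gGam, K)),
       ok = TRUE)
}

# --- optimizer wrapper ------------------------------------------------------

.optimize_deviance <- function(eval_fn, start, iter_max = 1000L) {
  cache <- new.env(parent = emptyenv())
  fn <- function(th) {
    r <- eval_fn(th)
    cache$th <- th
    cache$grad <- r$grad
    r$dev
  }
  gr <- function(th) {
    if (is.null(cache$th) || !identical(th, cache$th)) fn(th)
    cache$grad
  }
  res <- stats::nlminb(start, fn, gradient = gr,
                       control = list(iter.max = iter_max,
                                      eval.max = 3L * iter_max))
  res$grad_at_opt <- gr(res$par)
  res
}

# central-difference Hessian of the deviance from its analytic gradient
.num_hess <- function(eval_fn, theta, h_rel = 1e-4) {
  n <- length(theta)
  H <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- h_rel * (abs(theta[j]) + 1e-3)
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    H[, j] <- (eval_fn(tp)$grad - eval_fn(tm)$grad) / (2 * h)
  }
  (H + t(H)) / 2
}

# vcov of the free parameters: deviance = -2 loglik, so the observed
# information is half the deviance Hessian
.vcov_from_hess <- function(H) {
  V <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(V)) return(NULL)
  (V + t(V)) / 2
}

# --- starting values --------------------------------------------------------

# moment-based starts: ANOVA-score variances for the components, sample
# means for mu; falls back to crude fractions of the average dyad variance
# when too few complete families exist
.start_cov <- function(X) {
  start <- .theta_from_params(srm_parameters())
  v_avg <- mean(apply(X, 2L, stats::var, na.rm = TRUE), na.rm = TRUE)
  if (!is.finite(v_avg) || v_avg <= 0) v_avg <- 1
  cc <- stats::complete.cases(X)
  if (sum(cc) >= 10L) {
    sc <- unclass(anova_scores(X[cc, , drop = FALSE]))
    vfun <- function(j) max(stats::var(sc[, j]), 0.05 * v_avg)
    start[1L] <- vfun(1L)
    start[2:5] <- vapply(2:5, vfun, numeric(1L))
    start[6:9] <- vapply(6:9, vfun, numeric(1L))
    start[10:13] <- vapply(1:4, function(r) {
      cv <- stats::cov(sc[, 1L + r], sc[, 5L + r])
      sign(cv) * min(abs(cv), 0.9 * sqrt(start[1L + r] * start[5L + r]))
    }, numeric(1L))
    dy <- srm_dyads()
    vx <- apply(X, 2L, stats::var, na.rm = TRUE)
    start[14:25] <- pmax(vx - start[1L] - start[1L + match(.actor_of(dy), srm_roles())] -
                           start[5L + match(.partner_of(dy), srm_roles())],
                         0.1 * v_avg)
    start[26:31] <- 0
  } else {
    start[1L] <- 0.2 * v_avg
    start[2:5] <- 0.25 * v_avg
    start[6:9] <- 0.15 * v_avg
    start[10:13] <- 0
    start[14:25] <- 0.4 * v_avg
    start[26:31] <- 0
  }
  start
}

.start_mu <- function(X) {
  mu <- colMeans(X, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  mu
}
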