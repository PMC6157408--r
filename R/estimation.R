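#' Maximum-likelihood estimation of the SRM measurement model
#'
#' `fit_srm_ml()` fits the four-member SRM measurement model to complete
#' families only (incomplete families are excluded with a logged count);
#' `fit_srm_fiml()` maximizes the casewise (pattern-wise) observed-data
#' likelihood over all families with at least one observed dyad and is the
#' full-information maximum likelihood (FIML) estimator, valid under MAR
#' missingness.  On complete data the two fits coincide.
#'
#' The model has 43 free parameters: 13 factor (co)variances (family,
#' four actor, four partner variances, four generalized reciprocities),
#' 18 residual (co)variances (12 relationship variances, 6 dyadic
#' reciprocities), and a saturated 12-parameter mean structure that is
#' decomposed into the constrained SRM means after fitting.  Variances are
#' optimized unconstrained so improper (Heywood-type) solutions can occur;
#' a fit is flagged `converged` only when the optimizer reports success and
#' the fitted model-implied covariance matrix is positive definite.
#'
#' @param data An [srm_data] object.
#' @param start Optional named start vector for the 31 covariance-structure
#'   parameters (defaults to moment-based ANOVA-score starts).
#' @param compute_vcov Compute the observed-information covariance matrix
#'   of the estimates (disable for speed inside simulations).
#' @param quiet Suppress exclusion messages.
#' @return An object of class `srm_fit` with elements `params`
#'   (an [srm_parameters] estimate), `matrices` (model-implied
#'   `srm_matrices`), `theta` (named free-parameter vector), `vcov`,
#'   `loglik`, `converged`, `implied_pd`, `n_families`, `n_excluded`,
#'   `patterns` (missing-pattern census) and `method`.
#' @export
fit_srm_ml <- function(data, start = NULL, compute_vcov = TRUE, quiet = FALSE) {
  X <- .dyad_matrix(data)
  cc <- stats::complete.cases(X)
  if (sum(cc) < 2L)
    stop("fit_srm_ml needs at least 2 complete families", call. = FALSE)
  if (!quiet && any(!cc))
    message(sprintf("fit_srm_ml: excluded %d incomplete family(ies)", sum(!cc)))
  .fit_measurement(X[cc, , drop = FALSE], method = "ml",
                   n_excluded = sum(!cc), start = start,
                   compute_vcov = compute_vcov)
}

#' @rdname fit_srm_ml
#' @export
fit_srm_fiml <- function(data, start = NULL, compute_vcov = TRUE, quiet = FALSE) {
  X <- .dyad_matrix(data)
  empty <- rowSums(!is.na(X)) == 0L
  if (sum(!empty) < 2L)
    stop("fit_srm_fiml needs at least 2 families with >= 1 observed dyad",
         call. = FALSE)
  if (!quiet && any(empty))
    message(sprintf("fit_srm_fiml: excluded %d family(ies) with no observed dyads",
                    sum(empty)))
  .fit_measurement(X, method = "fiml", n_excluded = sum(empty), start = start,
                   compute_vcov = compute_vcov)
}

.fit_measurement <- function(X, method, n_excluded, start, compute_vcov) {
  Lam <- srm_loading_matrix()
  P <- .pattern_stats(X)
  th0 <- c(if (is.null(start)) .start_cov(X) else start, .start_mu(X))
  names(th0) <- c(.cov_par_names(), paste0("mu_", srm_dyads()))
  ev <- function(th) .meas_eval(th, P, Lam)
  res <- .optimize_deviance(ev, th0)
  .assemble_meas_fit(res, ev, P, method, n_excluded, compute_vcov)
}

.assemble_meas_fit <- function(res, ev, P, method, n_excluded, compute_vcov) {
  theta <- res$par
  ct <- .cov_from_theta(theta[1:31])
  mu <- theta[32:43]
  p0 <- srm_parameters(fam_var = theta[1L], act_var = theta[2:5],
                       par_var = theta[6:9], gen_recip = theta[10:13],
                       resid_var = theta[14:25], dyad_recip = theta[26:31])
  params <- .params_with_means(p0, mu)
  mats <- model_implied_moments(params)
  pd <- .is_pd(mats$sigma)
  vc <- NULL
  if (compute_vcov) vc <- .vcov_from_hess(.num_hess(ev, theta))
  if (!is.null(vc)) dimnames(vc) <- list(names(theta), names(theta))
  structure(list(params = params, matrices = mats, theta = theta, vcov = vc,
                 loglik = -res$objective / 2,
                 converged = (res$convergence == 0L) && pd,
                 implied_pd = pd, n_families = P$n, n_excluded = n_excluded,
                 patterns = P$census, method = method,
                 optim = res[c("convergence", "iterations", "message")]),
            class = "srm_fit")
}

#' @export
print.srm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("SRM fit (%s), %d families (%d excluded), loglik = %.3f\n",
              x$method, x$n_families, x$n_excluded, x$loglik))
  cat(sprintf("  converged: %s; implied covariance PD: %s\n",
              x$converged, x$implied_pd))
  print(x$params, digits = digits)
  if (!is.null(x$structural)) {
    cat("Structural coefficients:\n")
    print(structural_coefficients(x), digits = digits)
  }
  invisible(x)
}

#' @export
logLik.srm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), class = "logLik")
}

#' Joint structural equation fit of the SRM with antecedents or consequences
#'
#' Fits, by FIML, the one-step SEM comparator in which the SRM measurement
#' model and the structural regressions are estimated simultaneously.
#'
#' * `direction = "srm_as_predictor"`: each role-specific outcome `y_r` is
#'   regressed on the family effect and role r's actor and partner effects;
#'   the joint multivariate-normal model over the 12 dyads plus the
#'   observed outcomes is maximized.
#' * `direction = "srm_as_outcome"`: a MIMIC-type model in which the nine
#'   SRM effects are regressed on the observed predictors `z_1..z_K`
#'   (treated as fixed regressors).  For identification, the actor
#'   coefficients on each predictor are constrained to sum to zero, and
#'   likewise the partner coefficients: rows M, F, T are free and the S row
#'   is derived as minus their sum.
#'
#' @param data An [srm_data] object with `y_*` columns (predictor
#'   direction) or `z_*` columns (outcome direction).
#' @param direction `"srm_as_predictor"` or `"srm_as_outcome"`.
#' @param start Optional start vector for the covariance block.
#' @param compute_vcov Compute the observed-information vcov.
#' @param warm_start Start the measurement block from a preliminary
#'   [fit_srm_fiml()] fit (useful when the joint fit struggles).
#' @param quiet Suppress messages.
#' @return An `srm_fit` object additionally carrying a `structural` element;
#'   use [structural_coefficients()] for a coefficient table.
#' @export
fit_joint_sem <- function(data,
                          direction = c("srm_as_predictor", "srm_as_outcome"),
                          start = NULL, compute_vcov = TRUE,
                          warm_start = FALSE, quiet = FALSE) {
  direction <- match.arg(direction)
  if (direction == "srm_as_predictor")
    .fit_joint_predictor(data, start, compute_vcov, warm_start, quiet)
  else
    .fit_joint_mimic(data, start, compute_vcov, warm_start, quiet)
}

.warm_cov <- function(data, quiet) {
  f <- tryCatch(fit_srm_fiml(data, compute_vcov = FALSE, quiet = quiet),
                error = function(e) NULL)
  if (is.null(f)) NULL else f$theta[1:31]
}

.fit_joint_predictor <- function(data, start, compute_vcov, warm_start, quiet) {
  X <- .dyad_matrix(data)
  ycols <- paste0("y_", srm_roles())
  ycols <- ycols[ycols %in% names(data)]
  if (!length(ycols))
    stop("srm_as_predictor direction needs at least one y_<role> column",
         call. = FALSE)
  role_idx <- match(sub("^y_", "", ycols), srm_roles())
  Y <- as.matrix(data[, ycols, drop = FALSE])
  XY <- cbind(X, Y)
  empty <- rowSums(!is.na(XY)) == 0L
  if (!quiet && any(empty))
    message(sprintf("fit_joint_sem: excluded %d empty family(ies)", sum(empty)))
  P <- .pattern_stats(XY)
  m <- length(role_idx)
  Lam <- srm_loading_matrix()

  cov0 <- if (!is.null(start)) start
          else if (warm_start) .warm_cov(data, quiet = TRUE)
          else NULL
  if (is.null(cov0)) cov0 <- .start_cov(X)
  sl0 <- numeric(3L * m)
  vy0 <- numeric(m)
  cc <- stats::complete.cases(XY)
  sc <- if (sum(cc) >= 10L) unclass(anova_scores(X[cc, , drop = FALSE])) else NULL
  for (r in seq_len(m)) {
    ri <- role_idx[r]
    vy_all <- stats::var(Y[, r], na.rm = TRUE)
    if (!is.finite(vy_all) || vy_all <= 0) vy_all <- 1
    vy0[r] <- vy_all
    if (!is.null(sc)) {
      y <- Y[cc, r]
      lmres <- tryCatch(stats::lm(y ~ sc[, 1L] + sc[, 1L + ri] + sc[, 5L + ri]),
                        error = function(e) NULL)
      if (!is.null(lmres)) {
        b <- stats::coef(lmres)
        b[!is.finite(b)] <- 0
        sl0[3L * (r - 1L) + 1:3] <- b[2:4]
        vy0[r] <- max(stats::var(stats::residuals(lmres)), 0.25 * vy_all)
      }
    }
  }
  th0 <- c(cov0, sl0, vy0, .start_mu(X), colMeans(Y, na.rm = TRUE))
  slope_names <- as.vector(t(outer(sub("^y_", "", ycols), c("fam", "act", "par"),
                                   function(r, t) paste0("b_", r, "_", t))))
  names(th0) <- c(.cov_par_names(), slope_names, paste0("resid_var_y_", sub("^y_", "", ycols)),
                  paste0("mu_", srm_dyads()), paste0("intercept_y_", sub("^y_", "", ycols)))
  ev <- function(th) .joint_eval(th, P, Lam, role_idx)
  res <- .optimize_deviance(ev, th0)
  fit <- .assemble_meas_fit_joint(res, ev, P, n_excluded = sum(empty),
                                  compute_vcov = compute_vcov)
  fit$structural <- list(direction = "srm_as_predictor", roles = sub("^y_", "", ycols),
                         slope_names = slope_names)
  fit$method <- "sem_predictor"
  fit
}

# shared assembly for joint fits: covariance block + PD flag from the
# measurement part; full theta retained for wald tests
.assemble_meas_fit_joint <- function(res, ev, P, n_excluded, compute_vcov) {
  theta <- res$par
  p0 <- srm_parameters(fam_var = theta[1L], act_var = theta[2:5],
                       par_var = theta[6:9], gen_recip = theta[10:13],
                       resid_var = theta[14:25], dyad_recip = theta[26:31])
  mu <- theta[grep("^mu_", names(theta))]
  params <- .params_with_means(p0, mu)
  mats <- model_implied_moments(params)
  pd <- .is_pd(mats$sigma)
  vc <- NULL
  if (compute_vcov) vc <- .vcov_from_hess(.num_hess(ev, theta))
  if (!is.null(vc)) dimnames(vc) <- list(names(theta), names(theta))
  structure(list(params = params, matrices = mats, theta = theta, vcov = vc,
                 loglik = -res$objective / 2,
                 converged = (res$convergence == 0L) && pd,
                 implied_pd = pd, n_families = P$n, n_excluded = n_excluded,
                 patterns = P$census, method = "sem",
                 optim = res[c("convergence", "iterations", "message")]),
            class = "srm_fit")
}

.fit_joint_mimic <- function(data, start, compute_vcov, warm_start, quiet) {
  X <- .dyad_matrix(data)
  zcols <- grep("^z_", names(data), value = TRUE)
  if (!length(zcols))
    stop("srm_as_outcome direction needs z_* predictor columns", call. = FALSE)
  Z <- as.matrix(data[, zcols, drop = FALSE])
  K <- ncol(Z)
  okz <- stats::complete.cases(Z)
  if (!quiet && any(!okz))
    message(sprintf("fit_joint_sem: excluded %d family(ies) with missing predictors",
                    sum(!okz)))
  X <- X[okz, , drop = FALSE]
  Z <- Z[okz, , drop = FALSE]
  P <- .pattern_raw(X, Z)
  Lam <- srm_loading_matrix()
  cov0 <- if (!is.null(start)) start
          else if (warm_start) .warm_cov(srm_data(X), quiet = TRUE)
          else NULL
  if (is.null(cov0)) cov0 <- .start_cov(X)
  th0 <- c(cov0, .start_mu(X), numeric(7L * K))
  gnames <- c(paste0("gamma_Fam_", zcols),
              as.vector(t(outer(paste0("gamma_Act_", c("M", "F", "T")), zcols, paste, sep = "_"))),
              as.vector(t(outer(paste0("gamma_Par_", c("M", "F", "T")), zcols, paste, sep = "_"))))
  names(th0) <- c(.cov_par_names(), paste0("mu_", srm_dyads()), gnames)
  ev <- function(th) .mimic_eval(th, P, Lam, K)
  res <- .optimize_deviance(ev, th0)
  fit <- .assemble_meas_fit_joint(res, ev, P, n_excluded = sum(!okz),
                                  compute_vcov = compute_vcov)
  fit$structural <- list(direction = "srm_as_outcome", predictors = zcols, K = K,
                         gamma = .gamma_from_free(fit$theta[43L + seq_len(7L * K)], K))
  colnames(fit$structural$gamma) <- zcols
  fit$method <- "sem_mimic"
  fit
}

#' Wald tests for the free parameters of a fit
#'
#' @param fit A converged `srm_fit` with a computed vcov.
#' @return A data frame with columns `parameter`, `estimate`, `se`, `z`,
#'   `p` (two-sided normal p-values).
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "srm_fit"))
  if (!fit$converged)
    stop("refusing to compute Wald tests for a non-converged fit", call. = FALSE)
  if (is.null(fit$vcov))
    stop("fit has no vcov; refit with compute_vcov = TRUE", call. = FALSE)
  se <- sqrt(pmax(diag(fit$vcov), 0))
  z <- ifelse(se > 0, fit$theta / se, NA_real_)
  data.frame(parameter = names(fit$theta), estimate = unname(fit$theta),
             se = unname(se), z = unname(z),
             p = unname(2 * stats::pnorm(-abs(z))), row.names = NULL)
}

#' Structural coefficient table of a joint SEM fit
#'
#' For the predictor direction, returns the per-role slopes of each outcome
#' on the family, actor and partner effects.  For the outcome (MIMIC)
#' direction, returns the full 9 x K coefficient matrix in long form,
#' including the derived sibling rows (minus the sum of the M, F, T rows)
#' whose standard errors are obtained by the delta method.
#'
#' @param fit An `srm_fit` from [fit_joint_sem()].
#' @return A data frame with columns `effect`/`outcome`, `term`,
#'   `estimate`, `se`, `z`, `p`.
#' @export
structural_coefficients <- function(fit) {
  stopifnot(inherits(fit, "srm_fit"))
  st <- fit$structural
  if (is.null(st)) stop("fit has no structural part", call. = FALSE)
  th <- fit$theta
  V <- fit$vcov
  if (st$direction == "srm_as_predictor") {
    nm <- st$slope_names
    se <- if (is.null(V)) rep(NA_real_, length(nm)) else sqrt(pmax(diag(V)[nm], 0))
    parts <- do.call(rbind, strsplit(sub("^b_", "", nm), "_"))
    out <- data.frame(outcome = paste0("y_", parts[, 1L]), term = parts[, 2L],
                      estimate = unname(th[nm]), se = unname(se), row.names = NULL)
  } else {
    K <- st$K
    zc <- st$predictors
    fac <- srm_factors()
    rows <- list()
    for (k in seq_len(K)) {
      for (f in fac) {
        if (f %in% c("Act_S", "Par_S")) {
          base <- if (f == "Act_S") "gamma_Act_" else "gamma_Par_"
          nms <- paste0(base, c("M", "F", "T"), "_", zc[k])
          est <- -sum(th[nms])
          se <- if (is.null(V)) NA_real_ else sqrt(max(sum(V[nms, nms]), 0))
        } else {
          nm <- paste0("gamma_", f, "_", zc[k])
          est <- th[nm]
          se <- if (is.null(V)) NA_real_ else sqrt(max(V[nm, nm], 0))
        }
        rows[[length(rows) + 1L]] <- data.frame(effect = f, term = zc[k],
                                                estimate = unname(est),
                                                se = unname(se))
      }
    }
    out <- do.call(rbind, rows)
  }
  out$z <- ifelse(out$se > 0, out$estimate / out$se, NA_real_)
  out$p <- 2 * stats::pnorm(-abs(out$z))
  out
}
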