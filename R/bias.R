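#' Projection matrix behind the Bartlett-score bias
#'
#' Because the SRM loading matrix has rank 7, the pseudo-inverse Bartlett
#' score coefficients do not invert the loadings: instead
#' P = (Lambda' Theta^-1 Lambda)^+ Lambda' Theta^-1 Lambda is the rank-7
#' orthogonal projector onto the row space of Lambda.  Consequently
#' Bartlett scores are conditionally biased, E(eta_hat | eta) = P eta, and
#' regressions that use them as outcomes estimate P Gamma instead of Gamma.
#' P is invariant to the choice of positive-definite Theta.
#'
#' For the four-member SRM, P has (family, family) entry 2/3, (family,
#' actor/partner) entries 1/6, actor (and partner) diagonal 19/24,
#' same-type off-diagonals -5/24 and actor-partner entries 1/24
#' (0.667, 0.167, 0.792, -0.208, 0.042 at 3 decimals).
#'
#' @param loading Loading matrix (defaults to [srm_loading_matrix()]).
#' @param resid_cov Positive-definite residual covariance (defaults to the
#'   Theta of [srm_parameters()]).
#' @return An object of class `srm_projector`: list with `projector`
#'   (the full-precision matrix), `rank`, `is_symmetric`, `is_idempotent`,
#'   `theta_used`.
#' @examples
#' P <- bartlett_projection_matrix()
#' round(P$projector[1:3, 1:3], 3)
#' @export
bartlett_projection_matrix <- function(loading = srm_loading_matrix(),
                                       resid_cov = NULL) {
  if (is.null(resid_cov)) resid_cov <- .theta_matrix(srm_parameters())
  resid_cov <- as.matrix(resid_cov)
  if (!isTRUE(all.equal(resid_cov, t(resid_cov), tolerance = 1e-10)) ||
      !.is_pd(resid_cov))
    stop("resid_cov must be a symmetric positive-definite matrix", call. = FALSE)
  W <- chol2inv(chol(resid_cov))
  A <- crossprod(loading, W) %*% loading
  P <- .pinv(A) %*% A
  dimnames(P) <- list(colnames(loading), colnames(loading))
  structure(list(projector = P, rank = .mat_rank(P),
                 is_symmetric = max(abs(P - t(P))) < 1e-10,
                 is_idempotent = max(abs(P %*% P - P)) < 1e-10,
                 theta_used = resid_cov),
            class = "srm_projector")
}

#' @export
print.srm_projector <- function(x, ...) {
  cat(sprintf("Bartlett score projector: rank %d, symmetric: %s, idempotent: %s\n",
              x$rank, x$is_symmetric, x$is_idempotent))
  print(round(x$projector, 3))
  invisible(x)
}

.check_gamma_constraints <- function(gamma, tol = 1e-8) {
  gamma <- as.matrix(gamma)
  if (nrow(gamma) != 9L)
    stop("gamma must have 9 rows (one per SRM effect)", call. = FALSE)
  if (any(abs(colSums(gamma[2:5, , drop = FALSE])) > tol))
    stop("actor coefficients must sum to zero for every predictor",
         call. = FALSE)
  if (any(abs(colSums(gamma[6:9, , drop = FALSE])) > tol))
    stop("partner coefficients must sum to zero for every predictor",
         call. = FALSE)
  gamma
}

#' Analytically predicted coefficients for pseudo-inverse Bartlett scores
#'
#' When pseudo-inverse Bartlett factor scores are regressed on predictors
#' (SRM effects as outcomes), the expected coefficient matrix is P Gamma,
#' where P is the rank-7 projector of [bartlett_projection_matrix()] and
#' Gamma the true 9 x K coefficient matrix.  For any Gamma whose actor and
#' partner coefficients sum to zero per predictor, the expected family row
#' is 2/3 of the true family row.
#'
#' @param gamma True 9 x K coefficient matrix (rows ordered as
#'   [srm_factors()]), satisfying the zero-sum actor/partner constraints.
#' @param projector Optional `srm_projector` (defaults to the SRM one).
#' @return The 9 x K matrix of expected (biased) coefficients.
#' @export
predicted_bartlett_bias <- function(gamma, projector = NULL) {
  gamma <- .check_gamma_constraints(gamma)
  if (is.null(projector)) projector <- bartlett_projection_matrix()
  out <- projector$projector %*% gamma
  dimnames(out) <- dimnames(gamma)
  out
}

#' Numeric check of the regression-score unbiasedness identity
#'
#' When regression factor scores are used as predictors, the population
#' regression of an outcome on the scores recovers the true structural
#' coefficients because
#' (FSC_R Sigma FSC_R')^-1 FSC_R Lambda Psi = I.  This function evaluates
#' that identity from a set of measurement matrices and returns the
#' maximum absolute residual.  With a full-rank loading matrix the residual
#' is numerically zero; with the rank-deficient SRM loading matrix the
#' identity only holds on the identified (row-space) subspace, so both
#' sides are projected by the [bartlett_projection_matrix()] projector and
#' pseudo-inverses are used.
#'
#' @param fit A fitted model or list of measurement matrices.
#' @return The maximum absolute residual, with attribute `full_rank`.
#' @export
regression_identity_check <- function(fit) {
  m <- .as_meas(fit)
  # score weights always use the covariance implied by the supplied
  # components; m$sigma plays the role of the data covariance, so a
  # mismatch (e.g. a mis-specified loading matrix) breaks the identity
  sig_model <- m$loading %*% m$factor_cov %*% t(m$loading) + m$resid_cov
  ch <- tryCatch(chol(sig_model), error = function(e)
    stop("singular model-implied covariance", call. = FALSE))
  FSC <- m$factor_cov %*% crossprod(m$loading, chol2inv(ch))
  M1 <- FSC %*% m$sigma %*% t(FSC)
  M2 <- FSC %*% m$loading %*% m$factor_cov
  q <- ncol(m$loading)
  full_rank <- .mat_rank(m$loading) == q
  if (full_rank) {
    res <- max(abs(solve(M1, M2) - diag(q)))
  } else {
    P <- bartlett_projection_matrix(m$loading, m$resid_cov)$projector
    M1p <- P %*% M1 %*% P
    M2p <- P %*% M2 %*% P
    res <- max(abs(.pinv(M1p) %*% M2p - P))
  }
  structure(res, full_rank = full_rank)
}
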