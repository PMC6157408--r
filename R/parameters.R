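#' SRM parameter sets
#'
#' An `srm_parameters` object collects every parameter of the four-member
#' SRM measurement model: the family variance, role-specific actor and
#' partner variances, generalized reciprocities (covariance between the
#' same role's actor and partner effect), relationship(+error) variances
#' per dyad, dyadic reciprocities (covariance between the two residuals of
#' a reciprocal dyad pair), and the constrained mean structure.
#'
#' The defaults are the simulation conditions used throughout the package:
#' family variance 1, actor variances 1, partner variances 0.5,
#' relationship variances 1.5, generalized reciprocities +0.05 for M and T
#' and -0.05 for F and S, and dyadic reciprocities 0.02.
#'
#' Mean constraints (required for identification): actor means sum to zero,
#' partner means sum to zero, and relationship means are doubly centered
#' (for each actor the means over its three partners sum to zero, and for
#' each partner the means over its three actors sum to zero).
#'
#' @param fam_var Family-effect variance (scalar, >= 0 for generation).
#' @param act_var Actor variances; scalar or named vector over roles M,F,T,S.
#' @param par_var Partner variances; scalar or named vector over roles.
#' @param gen_recip Generalized reciprocities per role.
#' @param resid_var Relationship+error variances; scalar or vector over the
#'   12 dyads of [srm_dyads()].
#' @param dyad_recip Dyadic reciprocities; scalar or vector over the 6
#'   unordered pairs of [srm_dyad_pairs()].
#' @param mean_fam Family mean.
#' @param mean_act Actor means (sum to zero).
#' @param mean_par Partner means (sum to zero).
#' @param mean_rel Relationship means over the 12 dyads (doubly centered).
#' @return An object of class `srm_parameters` (a named list).
#' @examples
#' p <- srm_parameters()
#' variance_decomposition(p)
#' @export
srm_parameters <- function(fam_var = 1,
                           act_var = 1,
                           par_var = 0.5,
                           gen_recip = c(M = 0.05, F = -0.05, T = 0.05, S = -0.05),
                           resid_var = 1.5,
                           dyad_recip = 0.02,
                           mean_fam = 0,
                           mean_act = 0,
                           mean_par = 0,
                           mean_rel = 0) {
  roles <- srm_roles()
  dy <- srm_dyads()
  pr <- srm_dyad_pairs()
  p <- structure(list(
    fam_var    = as.numeric(fam_var)[1L],
    act_var    = .named_vec(act_var, roles, "act_var"),
    par_var    = .named_vec(par_var, roles, "par_var"),
    gen_recip  = .named_vec(gen_recip, roles, "gen_recip"),
    resid_var  = .named_vec(resid_var, dy, "resid_var"),
    dyad_recip = .named_vec(dyad_recip, pr, "dyad_recip"),
    mean_fam   = as.numeric(mean_fam)[1L],
    mean_act   = .named_vec(mean_act, roles, "mean_act"),
    mean_par   = .named_vec(mean_par, roles, "mean_par"),
    mean_rel   = .named_vec(mean_rel, dy, "mean_rel")
  ), class = "srm_parameters")
  .validate_srm_parameters(p)
  p
}

.named_vec <- function(x, nm, what) {
  x <- as.numeric(x)
  if (length(x) == 1L) x <- rep(x, length(nm))
  if (length(x) != length(nm))
    stop(sprintf("'%s' must have length 1 or %d", what, length(nm)), call. = FALSE)
  if (!is.null(names(x))) {
    if (!setequal(names(x), nm))
      stop(sprintf("names of '%s' must be %s", what, paste(nm, collapse = ", ")),
           call. = FALSE)
    x <- x[nm]
  } else names(x) <- nm
  x
}

.validate_srm_parameters <- function(p, tol = 1e-8) {
  if (abs(sum(p$mean_act)) > tol)
    stop("actor means must sum to zero", call. = FALSE)
  if (abs(sum(p$mean_par)) > tol)
    stop("partner means must sum to zero", call. = FALSE)
  dy <- srm_dyads()
  for (r in srm_roles()) {
    if (abs(sum(p$mean_rel[.actor_of(dy) == r])) > tol)
      stop(sprintf("relationship means for actor %s must sum to zero", r),
           call. = FALSE)
    if (abs(sum(p$mean_rel[.partner_of(dy) == r])) > tol)
      stop(sprintf("relationship means for partner %s must sum to zero", r),
           call. = FALSE)
  }
  invisible(p)
}

#' @export
print.srm_parameters <- function(x, digits = 3, ...) {
  cat("Four-member family SRM parameter set\n")
  cat("  family variance:       ", format(x$fam_var, digits = digits), "\n")
  cat("  actor variances:       ", paste(format(x$act_var, digits = digits), collapse = " "), "\n")
  cat("  partner variances:     ", paste(format(x$par_var, digits = digits), collapse = " "), "\n")
  cat("  generalized recip.:    ", paste(format(x$gen_recip, digits = digits), collapse = " "), "\n")
  cat("  relationship variances:", paste(format(x$resid_var, digits = digits), collapse = " "), "\n")
  cat("  dyadic reciprocities:  ", paste(format(x$dyad_recip, digits = digits), collapse = " "), "\n")
  cat("  family mean:           ", format(x$mean_fam, digits = digits), "\n")
  invisible(x)
}

# 9 x 9 factor covariance: diagonal variances plus the four same-role
# actor-partner covariances (generalized reciprocity)
.psi_matrix <- function(p) {
  Psi <- diag(c(p$fam_var, p$act_var, p$par_var))
  dimnames(Psi) <- list(srm_factors(), srm_factors())
  idx <- cbind(2:5, 6:9)
  Psi[idx] <- p$gen_recip
  Psi[idx[, 2:1]] <- p$gen_recip
  Psi
}

# 12 x 12 residual covariance: diagonal plus the six reciprocal-dyad
# covariances (dyadic reciprocity)
.theta_matrix <- function(p) {
  Theta <- diag(p$resid_var)
  dimnames(Theta) <- list(srm_dyads(), srm_dyads())
  pi <- .pair_index()
  Theta[pi] <- p$dyad_recip
  Theta[pi[, 2:1]] <- p$dyad_recip
  Theta
}

# 12-vector of dyad means implied by the constrained mean components
.mean_vector <- function(p) {
  dy <- srm_dyads()
  mu <- p$mean_fam + p$mean_act[.actor_of(dy)] + p$mean_par[.partner_of(dy)] +
    p$mean_rel
  names(mu) <- dy
  mu
}

#' Model-implied moments of the SRM measurement model
#'
#' Constructs the measurement matrices of the four-member SRM - loading
#' matrix Lambda, factor covariance Psi, residual covariance Theta and mean
#' vector mu - and the model-implied covariance
#' Sigma = Lambda Psi Lambda' + Theta.
#'
#' `factor_cov` / `resid_cov` may be supplied directly (overriding the
#' values in `params`); they are then checked against the SRM sparsity
#' patterns (Psi: diagonal plus same-role actor-partner covariances; Theta:
#' diagonal plus reciprocal-dyad covariances) and rejected on violation.
#'
#' @param params An [srm_parameters] object.
#' @param factor_cov Optional 9 x 9 replacement for Psi.
#' @param resid_cov Optional 12 x 12 replacement for Theta.
#' @return An object of class `srm_matrices`: list with elements `loading`,
#'   `factor_cov`, `resid_cov`, `mean_vector`, `sigma`.
#' @examples
#' m <- model_implied_moments(srm_parameters())
#' diag(m$sigma)   # 4.0 for every dyad under the default parameters
#' @export
model_implied_moments <- function(params, factor_cov = NULL, resid_cov = NULL) {
  stopifnot(inherits(params, "srm_parameters"))
  L <- srm_loading_matrix()
  Psi <- if (is.null(factor_cov)) .psi_matrix(params) else {
    .check_psi_pattern(factor_cov)
    factor_cov
  }
  Theta <- if (is.null(resid_cov)) .theta_matrix(params) else {
    .check_theta_pattern(resid_cov)
    resid_cov
  }
  mu <- .mean_vector(params)
  structure(list(loading = L, factor_cov = Psi, resid_cov = Theta,
                 mean_vector = mu, sigma = L %*% Psi %*% t(L) + Theta),
            class = "srm_matrices")
}

.check_psi_pattern <- function(Psi, tol = 1e-12) {
  if (!is.matrix(Psi) || !all(dim(Psi) == c(9L, 9L)))
    stop("factor covariance must be a 9 x 9 matrix", call. = FALSE)
  allowed <- diag(9L) == 1
  allowed[cbind(2:5, 6:9)] <- TRUE
  allowed[cbind(6:9, 2:5)] <- TRUE
  if (any(abs(Psi[!allowed]) > tol))
    stop("factor covariance violates the SRM pattern: only variances and ",
         "same-role actor-partner covariances may be nonzero", call. = FALSE)
  if (max(abs(Psi - t(Psi))) > tol) stop("factor covariance must be symmetric",
                                         call. = FALSE)
  invisible(Psi)
}

.check_theta_pattern <- function(Theta, tol = 1e-12) {
  if (!is.matrix(Theta) || !all(dim(Theta) == c(12L, 12L)))
    stop("residual covariance must be a 12 x 12 matrix", call. = FALSE)
  allowed <- diag(12L) == 1
  pi <- .pair_index()
  allowed[pi] <- TRUE
  allowed[pi[, 2:1]] <- TRUE
  if (any(abs(Theta[!allowed]) > tol))
    stop("residual covariance violates the SRM pattern: only variances and ",
         "reciprocal-dyad covariances may be nonzero", call. = FALSE)
  if (max(abs(Theta - t(Theta))) > tol) stop("residual covariance must be symmetric",
                                             call. = FALSE)
  invisible(Theta)
}

#' Variance decomposition per dyad
#'
#' Decomposes the model-implied variance of each dyadic measurement into
#' the shares contributed by the family, actor, partner, and
#' relationship(+error) components.  The four shares sum to one per dyad.
#'
#' @param params An [srm_parameters] object with nonnegative variances.
#' @return A data frame with one row per dyad and columns `dyad`, `family`,
#'   `actor`, `partner`, `relationship` (proportions of total variance).
#' @export
variance_decomposition <- function(params) {
  stopifnot(inherits(params, "srm_parameters"))
  if (params$fam_var < 0 || any(params$act_var < 0) || any(params$par_var < 0) ||
      any(params$resid_var < 0))
    stop("variance decomposition requires nonnegative variances", call. = FALSE)
  dy <- srm_dyads()
  comp <- cbind(family = rep(params$fam_var, 12L),
                actor = params$act_var[.actor_of(dy)],
                partner = params$par_var[.partner_of(dy)],
                relationship = params$resid_var)
  tot <- rowSums(comp)
  out <- data.frame(dyad = dy, comp / tot, row.names = NULL)
  out
}

#' Decompose a vector of dyad means into SRM mean components
#'
#' Given the 12 dyadic means, returns the unique decomposition into a
#' family mean (the average of the 12 entries), actor means, partner means
#' and doubly-centered relationship means satisfying the SRM identification
#' constraints.  Actor and partner means use the weighted row/column-mean
#' formulas of the two-way round-robin table with empty diagonal (family
#' size 4): actor_i = (9/8) rowmean_i + (3/8) colmean_i - (3/2) grand mean,
#' and symmetrically for partners.  Recomposing via
#' mu_ij = fam + act_i + par_j + rel_ij reproduces the input exactly.
#'
#' @param mu Numeric vector of length 12 ordered as [srm_dyads()].
#' @return A list with components `mean_fam`, `mean_act`, `mean_par`,
#'   `mean_rel`.
#' @export
srm_means_from_observed <- function(mu) {
  mu <- .as_dyad_vector(mu)
  dy <- srm_dyads()
  roles <- srm_roles()
  g <- mean(mu)
  rowm <- vapply(roles, function(r) mean(mu[.actor_of(dy) == r]), numeric(1L))
  colm <- vapply(roles, function(r) mean(mu[.partner_of(dy) == r]), numeric(1L))
  act <- 9 / 8 * rowm + 3 / 8 * colm - 3 / 2 * g
  par <- 9 / 8 * colm + 3 / 8 * rowm - 3 / 2 * g
  rel <- mu - g - act[.actor_of(dy)] - par[.partner_of(dy)]
  names(rel) <- dy
  list(mean_fam = g, mean_act = act, mean_par = par, mean_rel = rel)
}

.as_dyad_vector <- function(mu) {
  mu <- as.numeric(unlist(mu))
  if (length(mu) != 12L) stop("expected 12 dyadic values", call. = FALSE)
  names(mu) <- srm_dyads()
  mu
}

# parameter set -> srm_parameters with means taken from a mu vector
.params_with_means <- function(p, mu) {
  m <- srm_means_from_observed(mu)
  srm_parameters(fam_var = p$fam_var, act_var = p$act_var, par_var = p$par_var,
                 gen_recip = p$gen_recip, resid_var = p$resid_var,
                 dyad_recip = p$dyad_recip, mean_fam = m$mean_fam,
                 mean_act = m$mean_act, mean_par = m$mean_par,
                 mean_rel = m$mean_rel)
}
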