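# --- shared helpers ---------------------------------------------------------

# accept a fitted model, an srm_matrices object, or a plain list of
# measurement matrices (loading, factor_cov, resid_cov, mean_vector)
.as_meas <- function(fit) {
  if (inherits(fit, "srm_fit")) fit <- fit$matrices
  if (!is.list(fit) ||
      !all(c("loading", "factor_cov", "resid_cov", "mean_vector") %in% names(fit)))
    stop("expected a fitted model or a list with loading, factor_cov, ",
         "resid_cov, mean_vector", call. = FALSE)
  fit$loading <- as.matrix(fit$loading)
  fit$factor_cov <- as.matrix(fit$factor_cov)
  fit$resid_cov <- as.matrix(fit$resid_cov)
  if (is.null(fit$sigma))
    fit$sigma <- fit$loading %*% fit$factor_cov %*% t(fit$loading) + fit$resid_cov
  fit
}

# indicator matrix for scoring: srm_data -> 12 dyad columns; otherwise a
# bare numeric matrix whose columns match the loading rows (toy models)
.score_x <- function(data, p) {
  X <- if (inherits(data, "srm_data")) .dyad_matrix(data) else as.matrix(data)
  if (ncol(X) != p)
    stop(sprintf("data has %d indicator columns but the model has %d",
                 ncol(X), p), call. = FALSE)
  X
}

.new_scores <- function(scores, method, fsc, effective_rank = NULL,
                        centered = TRUE) {
  structure(scores, class = c("srm_scores", class(scores)),
            method = method, fsc = fsc, effective_rank = effective_rank,
            centered = centered)
}

#' @export
print.srm_scores <- function(x, ...) {
  cat(sprintf("SRM factor scores (method: %s), %d families x %d effects\n",
              attr(x, "method"), nrow(x), ncol(x)))
  cat(sprintf("  %d families with missing scores\n",
              sum(!stats::complete.cases(unclass(x)))))
  invisible(x)
}

# factor means (fam, act, par) implied by the model mean vector; only
# defined for the 12x9 SRM layout
.factor_means <- function(m) {
  if (!all(dim(m$loading) == c(12L, 9L))) {
    warning("add_means is only available for the 12 x 9 SRM model; ignored")
    return(numeric(9L))
  }
  d <- srm_means_from_observed(m$mean_vector)
  c(d$mean_fam, d$mean_act, d$mean_par)
}

# --- regression (Thurstone-Thomson) scores ----------------------------------

#' Regression factor scores
#'
#' Computes the regression (Thurstone-Thomson) factor scores
#' eta_hat = Psi Lambda' Sigma^-1 (x - mu) for every family with complete
#' indicators; families with any missing indicator get a missing score
#' vector.  When Psi and Theta are invertible this equals the equivalent
#' weighting (Psi^-1 + Lambda' Theta^-1 Lambda)^-1 Lambda' Theta^-1 (x - mu).
#'
#' @param fit A fitted SRM model ([fit_srm_ml()]/[fit_srm_fiml()]), an
#'   `srm_matrices` object, or a list of measurement matrices.
#' @param data An [srm_data] object (or a bare indicator matrix for
#'   non-SRM measurement models).
#' @param add_means Add the estimated factor means (family/actor/partner
#'   mean components of mu) back to the centered scores.
#' @return An `srm_scores` object: an n x q score matrix with attributes
#'   `method`, `fsc` (score-coefficient matrix per missing-data pattern)
#'   and `effective_rank`.
#' @export
regression_scores <- function(fit, data, add_means = FALSE) {
  m <- .as_meas(fit)
  X <- .score_x(data, nrow(m$loading))
  ch <- tryCatch(chol(m$sigma), error = function(e)
    stop("model-implied covariance matrix Sigma is singular; cannot compute ",
         "regression scores", call. = FALSE))
  FSC <- m$factor_cov %*% crossprod(m$loading, chol2inv(ch))
  rownames(FSC) <- colnames(m$loading)
  sc <- matrix(NA_real_, nrow(X), ncol(m$loading),
               dimnames = list(rownames(X), colnames(m$loading)))
  cc <- stats::complete.cases(X)
  if (any(cc))
    sc[cc, ] <- sweep(X[cc, , drop = FALSE], 2L, m$mean_vector) %*% t(FSC)
  if (add_means) sc <- sweep(sc, 2L, .factor_means(m), `+`)
  .new_scores(sc, "regression", list(complete = FSC),
              effective_rank = c(complete = ncol(m$loading)),
              centered = !add_means)
}

#' Regression factor scores under missing data (FIML)
#'
#' Per missing-data pattern, the loading matrix, residual covariance and
#' mean vector are subset to the observed indicators and the regression
#' weighting applied:
#' eta_hat = Psi Lambda_o' Sigma_o^-1 (x_o - mu_o), with
#' Sigma_o = Lambda_o Psi Lambda_o' + Theta_o.  Families with all
#' indicators observed reproduce [regression_scores()] exactly; families
#' with no observed indicator are shrunk fully to the factor mean (score
#' zero) with a warning.
#'
#' @inheritParams regression_scores
#' @return An `srm_scores` object with one score-coefficient matrix per
#'   observed pattern.
#' @export
regression_fiml_scores <- function(fit, data, add_means = FALSE) {
  m <- .as_meas(fit)
  X <- .score_x(data, nrow(m$loading))
  q <- ncol(m$loading)
  sc <- matrix(NA_real_, nrow(X), q,
               dimnames = list(rownames(X), colnames(m$loading)))
  obs <- !is.na(X)
  key <- apply(obs, 1L, paste0, collapse = "")
  fsc <- list()
  n_empty <- 0L
  for (k in unique(key)) {
    rows <- which(key == k)
    idx <- which(obs[rows[1L], ])
    if (!length(idx)) {
      sc[rows, ] <- 0
      n_empty <- n_empty + length(rows)
      next
    }
    Lo <- m$loading[idx, , drop = FALSE]
    So <- Lo %*% m$factor_cov %*% t(Lo) + m$resid_cov[idx, idx, drop = FALSE]
    Fp <- m$factor_cov %*% crossprod(Lo, chol2inv(chol(So)))
    dimnames(Fp) <- list(colnames(m$loading), rownames(m$loading)[idx])
    fsc[[k]] <- Fp
    sc[rows, ] <- sweep(X[rows, idx, drop = FALSE], 2L, m$mean_vector[idx]) %*% t(Fp)
  }
  if (n_empty > 0L)
    warning(sprintf("%d family(ies) with no observed indicators scored at the factor mean",
                    n_empty))
  if (add_means) sc <- sweep(sc, 2L, .factor_means(m), `+`)
  .new_scores(sc, "regression_fiml", fsc, centered = !add_means)
}

# --- Bartlett scores --------------------------------------------------------

#' Bartlett factor scores
#'
#' Computes Bartlett factor scores in one of three variants:
#' * `"residual"`: (Lambda' Theta^-1 Lambda)^-1 Lambda' Theta^-1 (x - mu),
#' * `"gls"`: (Lambda' Sigma^-1 Lambda)^-1 Lambda' Sigma^-1 (x - mu)
#'   (equivalent to the residual variant when the system is full rank),
#' * `"pinv"`: (Lambda' Theta^-1 Lambda)^+ Lambda' Theta^-1 (x - mu) using
#'   the Moore-Penrose pseudo-inverse.
#'
#' For the SRM loading matrix the 9 x 9 system Lambda' Theta^-1 Lambda has
#' rank 7, so the residual and GLS variants fail with an explicit rank
#' error; only the pseudo-inverse variant is defined.  Families with
#' missing indicators get missing scores (use [bartlett_fiml_scores()]).
#'
#' @inheritParams regression_scores
#' @param variant One of `"pinv"`, `"residual"`, `"gls"`.
#' @return An `srm_scores` object.
#' @export
bartlett_scores <- function(fit, data, variant = c("pinv", "residual", "gls"),
                            add_means = FALSE) {
  variant <- match.arg(variant)
  m <- .as_meas(fit)
  X <- .score_x(data, nrow(m$loading))
  q <- ncol(m$loading)
  W <- switch(variant,
              pinv = ,
              residual = chol2inv(chol(m$resid_cov)),
              gls = chol2inv(chol(m$sigma)))
  A <- crossprod(m$loading, W) %*% m$loading
  rk <- .mat_rank(A)
  if (variant %in% c("residual", "gls")) {
    if (rk < q)
      stop(sprintf(paste0("the %d x %d Bartlett system Lambda' %s^-1 Lambda has rank %d < %d ",
                          "(rank-deficient loading matrix); use variant = 'pinv'"),
                   q, q, if (variant == "gls") "Sigma" else "Theta", rk, q),
           call. = FALSE)
    Ainv <- chol2inv(chol(A))
  } else {
    Ainv <- .pinv(A)
  }
  FSC <- Ainv %*% crossprod(m$loading, W)
  dimnames(FSC) <- list(colnames(m$loading), rownames(m$loading))
  sc <- matrix(NA_real_, nrow(X), q,
               dimnames = list(rownames(X), colnames(m$loading)))
  cc <- stats::complete.cases(X)
  if (any(cc))
    sc[cc, ] <- sweep(X[cc, , drop = FALSE], 2L, m$mean_vector) %*% t(FSC)
  if (add_means) sc <- sweep(sc, 2L, .factor_means(m), `+`)
  .new_scores(sc, paste0("bartlett_", variant), list(complete = FSC),
              effective_rank = c(complete = rk), centered = !add_means)
}

#' Bartlett factor scores under missing data (FIML)
#'
#' Per missing-data pattern, subsets Lambda, Theta and mu to the observed
#' indicators and applies the pseudo-inverse Bartlett weighting
#' (Lambda_o' Theta_o^-1 Lambda_o)^+ Lambda_o' Theta_o^-1 (x_o - mu_o).
#' The complete pattern reproduces `bartlett_scores(variant = "pinv")`
#' exactly.  Families with no observed indicators get missing scores:
#' unlike the regression estimator, the Bartlett estimator has no prior
#' mean to shrink to.
#'
#' @inheritParams regression_scores
#' @return An `srm_scores` object whose `effective_rank` attribute records
#'   the rank of the score system for each observed pattern.
#' @export
bartlett_fiml_scores <- function(fit, data, add_means = FALSE) {
  m <- .as_meas(fit)
  X <- .score_x(data, nrow(m$loading))
  q <- ncol(m$loading)
  sc <- matrix(NA_real_, nrow(X), q,
               dimnames = list(rownames(X), colnames(m$loading)))
  obs <- !is.na(X)
  key <- apply(obs, 1L, paste0, collapse = "")
  fsc <- list()
  erank <- numeric(0)
  for (k in unique(key)) {
    rows <- which(key == k)
    idx <- which(obs[rows[1L], ])
    if (!length(idx)) next  # no observed indicators: scores stay missing
    Lo <- m$loading[idx, , drop = FALSE]
    Wi <- chol2inv(chol(m$resid_cov[idx, idx, drop = FALSE]))
    A <- crossprod(Lo, Wi) %*% Lo
    Fp <- .pinv(A) %*% crossprod(Lo, Wi)
    dimnames(Fp) <- list(colnames(m$loading), rownames(m$loading)[idx])
    fsc[[k]] <- Fp
    erank[k] <- .mat_rank(A)
    sc[rows, ] <- sweep(X[rows, idx, drop = FALSE], 2L, m$mean_vector[idx]) %*% t(Fp)
  }
  if (add_means) sc <- sweep(sc, 2L, .factor_means(m), `+`)
  .new_scores(sc, "bartlett_fiml", fsc, effective_rank = erank,
              centered = !add_means)
}

# --- ANOVA scores -----------------------------------------------------------

#' Classical weighted ANOVA scores
#'
#' Computes the weighted sum scores from each family's own 4 x 4 round-robin
#' table (empty diagonal): the family score is the grand mean of the 12
#' entries, and for family size n = 4
#' actor_i = (9/8) rowmean_i + (3/8) colmean_i - (3/2) grand mean,
#' partner_i = (9/8) colmean_i + (3/8) rowmean_i - (3/2) grand mean.
#' If any dyadic measurement is missing, no ANOVA score can be obtained and
#' the family's nine scores are all missing.  Unlike the model-based
#' scores, ANOVA scores are computed on the raw values (the family score
#' contains the family mean).
#'
#' @param data An [srm_data] object or an n x 12 matrix of dyad values.
#' @return An `srm_scores` object.
#' @export
anova_scores <- function(data) {
  X <- .score_x(data, 12L)
  dy <- srm_dyads()
  roles <- srm_roles()
  # averaging maps: rows of FSC give each score as a weighting of the 12 cells
  Wrow <- vapply(roles, function(r) (.actor_of(dy) == r) / 3, numeric(12L))
  Wcol <- vapply(roles, function(r) (.partner_of(dy) == r) / 3, numeric(12L))
  FSC <- rbind(Fam = rep(1 / 12, 12L),
               t(9 / 8 * Wrow + 3 / 8 * Wcol - 3 / 2 / 12),
               t(9 / 8 * Wcol + 3 / 8 * Wrow - 3 / 2 / 12))
  rownames(FSC) <- srm_factors()
  colnames(FSC) <- dy
  sc <- matrix(NA_real_, nrow(X), 9L,
               dimnames = list(rownames(X), srm_factors()))
  cc <- stats::complete.cases(X)
  if (any(cc)) sc[cc, ] <- X[cc, , drop = FALSE] %*% t(FSC)
  .new_scores(sc, "anova", list(complete = FSC),
              effective_rank = c(complete = .mat_rank(FSC)), centered = FALSE)
}

#' Write a factor score set to CSV
#'
#' Writes `family_id`, `method`, then the nine labeled score columns;
#' missing scores are written as empty fields.
#'
#' @param scores An `srm_scores` object.
#' @param path Output path.
#' @export
write_scores_csv <- function(scores, path) {
  stopifnot(inherits(scores, "srm_scores"))
  df <- data.frame(family_id = rownames(scores),
                   method = attr(scores, "method"),
                   unclass(scores), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
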