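# factor-score-regression pipelines (step 3 of the two-step approach)

.fsr_result <- function(df, direction, method, n_used, n_dropped,
                        se_bootstrap = NULL, B = NULL, seed = NULL) {
  if (!is.null(se_bootstrap)) {
    df$se_bootstrap <- se_bootstrap
    df$ci_lo_boot <- df$estimate - 1.96 * se_bootstrap
    df$ci_hi_boot <- df$estimate + 1.96 * se_bootstrap
  }
  structure(df, class = c("srm_fsr", "data.frame"), direction = direction,
            method = method, n_used = n_used, n_dropped = n_dropped,
            B = B, seed = seed)
}

#' Factor-score regression with SRM effects as predictors
#'
#' Step 3 of the two-step pipeline for the predictor direction: ordinary
#' least squares of a role-specific outcome `y_r` on the family score and
#' role r's actor and partner scores (with intercept).  Naive standard
#' errors are the classical homoskedastic OLS standard errors, which treat
#' the scores as measured without error; see [fsr_bootstrap()] for
#' family-bootstrap standard errors.  Families with missing scores or
#' outcome are dropped listwise with a logged count.
#'
#' @param scores An `srm_scores` object (any method).
#' @param data The [srm_data] object carrying the `y_<role>` column.
#' @param role One of `"M"`, `"F"`, `"T"`, `"S"`.
#' @param quiet Suppress the exclusion message.
#' @return An `srm_fsr` data frame with columns `term`, `estimate`,
#'   `se_naive`, `ci_lo`, `ci_hi` and attributes `n_used`, `n_dropped`.
#' @export
fsr_predictor <- function(scores, data, role, quiet = FALSE) {
  stopifnot(inherits(scores, "srm_scores"))
  role <- match.arg(role, srm_roles())
  ycol <- paste0("y_", role)
  if (!ycol %in% names(data))
    stop(sprintf("outcome column %s not present", ycol), call. = FALSE)
  ri <- match(role, srm_roles())
  sc <- unclass(scores)
  df <- data.frame(y = data[[ycol]], fam = sc[, 1L], act = sc[, 1L + ri],
                   par = sc[, 5L + ri])
  cc <- stats::complete.cases(df)
  if (sum(cc) < 5L)
    stop(sprintf("only %d usable families (need >= 5)", sum(cc)), call. = FALSE)
  if (!quiet && any(!cc))
    message(sprintf("fsr_predictor: dropped %d family(ies) with missing scores/outcome",
                    sum(!cc)))
  fit <- stats::lm(y ~ fam + act + par, data = df[cc, ])
  cf <- summary(fit)$coefficients
  out <- data.frame(term = c("(Intercept)", "fam", paste0("act_", role),
                             paste0("par_", role)),
                    estimate = unname(cf[, 1L]), se_naive = unname(cf[, 2L]))
  out$ci_lo <- out$estimate - 1.96 * out$se_naive
  out$ci_hi <- out$estimate + 1.96 * out$se_naive
  .fsr_result(out, "srm_as_predictor", attr(scores, "method"),
              n_used = sum(cc), n_dropped = sum(!cc))
}

#' Factor-score regression with SRM effects as outcomes
#'
#' Step 3 for the outcome direction: each of the nine SRM effect scores is
#' regressed by OLS on the external predictors (with intercept).
#'
#' @param scores An `srm_scores` object.
#' @param data The [srm_data] object carrying the predictor columns.
#' @param predictors Character vector of predictor column names (defaults
#'   to all `z_*` columns).
#' @param quiet Suppress the exclusion message.
#' @return An `srm_fsr` data frame with columns `effect`, `term`,
#'   `estimate`, `se_naive`, `ci_lo`, `ci_hi`.
#' @export
fsr_outcome <- function(scores, data, predictors = NULL, quiet = FALSE) {
  stopifnot(inherits(scores, "srm_scores"))
  if (is.null(predictors)) predictors <- grep("^z_", names(data), value = TRUE)
  if (!length(predictors) || !all(predictors %in% names(data)))
    stop("predictor columns not present", call. = FALSE)
  Z <- as.matrix(data[, predictors, drop = FALSE])
  sc <- unclass(scores)
  cc <- stats::complete.cases(cbind(sc, Z))
  if (sum(cc) < 5L)
    stop(sprintf("only %d usable families (need >= 5)", sum(cc)), call. = FALSE)
  if (!quiet && any(!cc))
    message(sprintf("fsr_outcome: dropped %d family(ies) with missing scores/predictors",
                    sum(!cc)))
  rows <- list()
  for (f in seq_len(ncol(sc))) {
    fit <- stats::lm(sc[cc, f] ~ Z[cc, , drop = FALSE])
    cf <- summary(fit)$coefficients
    rows[[f]] <- data.frame(effect = colnames(sc)[f],
                            term = c("(Intercept)", predictors),
                            estimate = unname(cf[, 1L]),
                            se_naive = unname(cf[, 2L]))
  }
  out <- do.call(rbind, rows)
  out$ci_lo <- out$estimate - 1.96 * out$se_naive
  out$ci_hi <- out$estimate + 1.96 * out$se_naive
  .fsr_result(out, "srm_as_outcome", attr(scores, "method"),
              n_used = sum(cc), n_dropped = sum(!cc))
}

# fit measurement model + scores for one method tag
.fit_and_score <- function(data, method, quiet = TRUE) {
  if (method == "anova") return(list(scores = anova_scores(data), converged = TRUE))
  fiml <- method %in% c("regression_fiml", "bartlett_fiml")
  fit <- if (fiml) fit_srm_fiml(data, compute_vcov = FALSE, quiet = quiet)
         else fit_srm_ml(data, compute_vcov = FALSE, quiet = quiet)
  sc <- switch(method,
               regression = regression_scores(fit, data),
               regression_fiml = suppressWarnings(regression_fiml_scores(fit, data)),
               bartlett_pinv = bartlett_scores(fit, data, variant = "pinv"),
               bartlett_fiml = bartlett_fiml_scores(fit, data),
               stop("unknown score method: ", method, call. = FALSE))
  list(scores = sc, converged = fit$converged, fit = fit)
}

#' Family-bootstrap standard errors for a factor-score regression
#'
#' Resamples families with replacement, re-estimates the measurement
#' model, the factor scores and the step-3 regression on every resample,
#' and reports the standard deviation of the bootstrap coefficient draws.
#' This acknowledges that factor scores are estimated with error, which the
#' naive OLS standard errors ignore.  Resamples whose measurement fit does
#' not converge are redrawn, with a cap of `3 * B` attempts.
#'
#' @param data An [srm_data] object.
#' @param method Score method: one of `"regression"`, `"regression_fiml"`,
#'   `"bartlett_pinv"`, `"bartlett_fiml"`, `"anova"`.
#' @param direction `"srm_as_predictor"` or `"srm_as_outcome"`.
#' @param role Outcome role (predictor direction only).
#' @param predictors Predictor columns (outcome direction only).
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed RNG seed; a fixed seed makes the result bit-reproducible.
#' @return The point-estimate `srm_fsr` table augmented with
#'   `se_bootstrap` and bootstrap confidence limits.
#' @export
fsr_bootstrap <- function(data, method, direction = c("srm_as_predictor", "srm_as_outcome"),
                          role = NULL, predictors = NULL, B = 500L, seed = NULL) {
  direction <- match.arg(direction)
  if (B < 100L) stop("B must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  run_one <- function(d) {
    fs <- .fit_and_score(d, method)
    if (!fs$converged) return(NULL)
    res <- if (direction == "srm_as_predictor")
      fsr_predictor(fs$scores, d, role, quiet = TRUE)
    else
      fsr_outcome(fs$scores, d, predictors, quiet = TRUE)
    list(res = res, est = res$estimate)
  }
  base <- run_one(data)
  if (is.null(base)) stop("measurement model did not converge on the full data",
                          call. = FALSE)
  n <- nrow(data)
  draws <- matrix(NA_real_, B, length(base$est))
  got <- 0L
  attempts <- 0L
  while (got < B) {
    attempts <- attempts + 1L
    if (attempts > 3L * B)
      stop(sprintf("bootstrap exceeded %d attempts with %d converged resamples",
                   3L * B, got), call. = FALSE)
    idx <- sample.int(n, n, replace = TRUE)
    d_b <- data[idx, , drop = FALSE]
    d_b$family_id <- seq_len(n)
    d_b <- suppressMessages(srm_data(d_b))
    r <- tryCatch(suppressMessages(run_one(d_b)), error = function(e) NULL)
    if (is.null(r)) next
    got <- got + 1L
    draws[got, ] <- r$est
  }
  .fsr_result(as.data.frame(base$res), direction, method,
              n_used = attr(base$res, "n_used"),
              n_dropped = attr(base$res, "n_dropped"),
              se_bootstrap = apply(draws, 2L, stats::sd), B = B, seed = seed)
}
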