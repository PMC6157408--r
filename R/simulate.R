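# synthetic-data generation for the two study conditions, the quartile-
# conditional missingness mechanisms, and the Monte-Carlo harness

.chol_or_stop <- function(M, what) {
  tryCatch(chol(M), error = function(e)
    stop(sprintf("%s is not positive definite; invalid parameter combination",
                 what), call. = FALSE))
}

#' Default structural coefficients for the predictor-direction condition
#'
#' Each role-specific outcome is regressed on the family effect and the
#' role's own actor and partner effects.  The defaults use slope 0.3 on the
#' family effect, 0.2 on the actor effect and 0 on the partner effect for
#' every role (the zero slope supports type-I-error checks), intercept 0
#' and unit outcome residual variance.
#'
#' @return A list with `coef` (4 x 3 matrix, rows = roles, columns
#'   `fam`, `act`, `par`), `intercept` (length 4) and `resid_var`
#'   (length 4).
#' @export
default_predictor_gamma <- function() {
  coef <- matrix(rep(c(0.3, 0.2, 0), each = 4L), 4L, 3L,
                 dimnames = list(srm_roles(), c("fam", "act", "par")))
  list(coef = coef,
       intercept = stats::setNames(numeric(4L), srm_roles()),
       resid_var = stats::setNames(rep(1, 4L), srm_roles()))
}

#' Default structural coefficients for the outcome-direction condition
#'
#' The nine SRM effects are regressed on three standard-normal predictors.
#' The family row is (0.021, -0.005, -0.094); the partner rows are zero and
#' the actor rows are nonzero but sum to zero per predictor, as the
#' identification constraints require.
#'
#' @return A 9 x 3 coefficient matrix (rows ordered as [srm_factors()]).
#' @export
default_outcome_gamma <- function() {
  G <- matrix(0, 9L, 3L, dimnames = list(srm_factors(), paste0("z_", 1:3)))
  G[1L, ] <- c(0.021, -0.005, -0.094)
  G["Act_M", ] <- c(0.20, 0.10, 0.00)
  G["Act_F", ] <- c(-0.10, 0.05, 0.10)
  G["Act_T", ] <- c(0.10, -0.20, 0.05)
  G["Act_S", ] <- -colSums(G[c("Act_M", "Act_F", "Act_T"), ])
  G
}

# draw latent effects and residuals and assemble the 12 dyad columns
.draw_measurement <- function(n, params, eta_shift = NULL) {
  m <- model_implied_moments(params)
  cP <- .chol_or_stop(m$factor_cov, "factor covariance")
  cT <- .chol_or_stop(m$resid_cov, "residual covariance")
  eta <- matrix(stats::rnorm(n * 9L), n, 9L) %*% cP
  if (!is.null(eta_shift)) eta <- eta + eta_shift
  eps <- matrix(stats::rnorm(n * 12L), n, 12L) %*% cT
  X <- sweep(eta %*% t(m$loading) + eps, 2L, m$mean_vector, `+`)
  colnames(eta) <- srm_factors()
  list(X = X, eta = eta)
}

#' Generate data for the SRM-as-predictor condition
#'
#' Draws four-member families from the SRM measurement model (default
#' variance components: family 1, actor 1, partner 0.5, relationship 1.5,
#' generalized reciprocities +/-0.05, dyadic reciprocities 0.02) and
#' creates role-specific outcomes
#' `y_r = intercept + b_fam Fam + b_act Act_r + b_par Par_r + noise`.
#'
#' @param n Number of families.
#' @param params An [srm_parameters] object.
#' @param gamma Structural coefficients as in [default_predictor_gamma()].
#' @param seed Optional RNG seed.
#' @return An [srm_data] object with `y_M` ... `y_S` columns; the latent
#'   effect draws are attached as attribute `"latent"` for diagnostics.
#' @export
generate_predictor_condition <- function(n, params = srm_parameters(),
                                         gamma = default_predictor_gamma(),
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dm <- .draw_measurement(n, params)
  Y <- vapply(seq_len(4L), function(r) {
    gamma$intercept[r] +
      gamma$coef[r, 1L] * dm$eta[, 1L] +
      gamma$coef[r, 2L] * dm$eta[, 1L + r] +
      gamma$coef[r, 3L] * dm$eta[, 5L + r] +
      stats::rnorm(n, sd = sqrt(gamma$resid_var[r]))
  }, numeric(n))
  colnames(Y) <- paste0("y_", srm_roles())
  out <- srm_data(dm$X, outcomes = Y)
  attr(out, "latent") <- dm$eta
  out
}

#' Generate data for the SRM-as-outcome (MIMIC) condition
#'
#' Draws standard-normal predictors `z_1..z_K`, sets the latent SRM effects
#' to `Gamma z` plus an SRM-structured disturbance, and emits the 12 dyadic
#' measurements.  `gamma` must satisfy the zero-sum actor/partner
#' constraints.
#'
#' @param n Number of families.
#' @param params An [srm_parameters] object (disturbance covariances).
#' @param gamma 9 x K structural coefficient matrix
#'   (default [default_outcome_gamma()]).
#' @param seed Optional RNG seed.
#' @return An [srm_data] object with `z_*` columns and a `"latent"`
#'   attribute.
#' @export
generate_outcome_condition <- function(n, params = srm_parameters(),
                                       gamma = default_outcome_gamma(),
                                       seed = NULL) {
  gamma <- .check_gamma_constraints(gamma)
  K <- ncol(gamma)
  if (!is.null(seed)) set.seed(seed)
  Z <- matrix(stats::rnorm(n * K), n, K,
              dimnames = list(NULL, paste0("z_", seq_len(K))))
  dm <- .draw_measurement(n, params, eta_shift = Z %*% t(gamma))
  out <- srm_data(dm$X, predictors = Z)
  attr(out, "latent") <- dm$eta
  out
}

# mechanism definitions: which dyads are deletable, at what rate, and
# which observed variable's first quartile defines the eligible stratum
.missing_mechanisms <- function() {
  list(
    pred_dyad = list(cols = c("x_TM", "x_TF"), rate = 0.25, cond = "x_TS"),
    pred_outcome = list(cols = c("x_TM", "x_TF", "x_TS"), rate = 0.25, cond = "y_T"),
    out_dyad = list(cols = c("x_TM", "x_TF", "x_TS", "x_FM", "x_FT", "x_FS"),
                    rate = 0.40, cond = "x_SM"),
    out_predictor = list(
      list(cols = c("x_TM", "x_TF", "x_TS", "x_FM", "x_FT", "x_FS"),
           rate = 0.40, cond = "z_1"),
      list(cols = c("x_TM", "x_TF", "x_TS", "x_MF", "x_MT", "x_MS"),
           rate = 0.40, cond = "z_2"))
  )
}

#' Apply a quartile-conditional missingness mechanism
#'
#' Deletes dyadic measurements cell-wise and independently at the stated
#' rate, but only in families where the mechanism's conditioning variable
#' falls strictly below its empirical first quartile:
#' * `"pred_dyad"`: `x_TM`, `x_TF` at 25% when `x_TS` < Q1 (MAR given the
#'   dyads),
#' * `"pred_outcome"`: `x_TM`, `x_TF`, `x_TS` at 25% when `y_T` < Q1,
#' * `"out_dyad"`: the six target/father dyads at 40% when `x_SM` < Q1,
#' * `"out_predictor"`: the six target/father dyads at 40% when `z_1` < Q1,
#'   plus the six target/mother dyads at 40% when `z_2` < Q1,
#' * `"none"`: no deletion.
#'
#' The first quartile is the empirical `stats::quantile()` (type 7) of the
#' conditioning variable over the generated sample.
#'
#' @param data An [srm_data] object.
#' @param mechanism Mechanism name (see above).
#' @param seed Optional RNG seed.
#' @param rate Optional overriding deletion rate.
#' @return The data with deleted cells set to `NA`.
#' @export
apply_missingness <- function(data, mechanism = c("none", "pred_dyad",
                                                  "pred_outcome", "out_dyad",
                                                  "out_predictor"),
                              seed = NULL, rate = NULL) {
  mechanism <- match.arg(mechanism)
  if (mechanism == "none") return(data)
  if (!is.null(seed)) set.seed(seed)
  stages <- .missing_mechanisms()[[mechanism]]
  if (!is.null(stages$cols)) stages <- list(stages)
  for (st in stages) {
    if (!st$cond %in% names(data))
      stop(sprintf("conditioning variable %s not present in data", st$cond),
           call. = FALSE)
    r <- if (is.null(rate)) st$rate else rate
    v <- data[[st$cond]]
    q1 <- stats::quantile(v, 0.25, na.rm = TRUE, names = FALSE)
    eligible <- which(!is.na(v) & v < q1)
    for (cl in st$cols) {
      del <- eligible[stats::runif(length(eligible)) < r]
      data[[cl]][del] <- NA_real_
    }
  }
  data
}

#' Simulation configuration
#'
#' Collects everything a Monte-Carlo run needs: the study condition, sample
#' size, number of replicates, master seed, missingness mechanism, methods
#' to compare, and the generating parameters.  An identical configuration
#' and seed yields a bit-identical summary.
#'
#' @param condition `"srm_as_predictor"` or `"srm_as_outcome"`.
#' @param n_families Families per replicate (the study sizes are 50 / 500).
#' @param reps Number of Monte-Carlo replicates.
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param missing Missingness mechanism for [apply_missingness()].
#' @param methods Subset of `"sem"`, `"regression"`, `"bartlett_pinv"`,
#'   `"regression_fiml"`, `"bartlett_fiml"`, `"anova"`.
#' @param params Generating [srm_parameters].
#' @param gamma Structural coefficients (see the generators).
#' @return A list of class `srm_sim_config`.
#' @export
srm_sim_config <- function(condition = c("srm_as_predictor", "srm_as_outcome"),
                           n_families = 500L, reps = 1000L, seed = 1L,
                           missing = "none",
                           methods = c("sem", "regression", "bartlett_pinv",
                                       "regression_fiml", "bartlett_fiml",
                                       "anova"),
                           params = srm_parameters(), gamma = NULL) {
  condition <- match.arg(condition)
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(gamma))
    gamma <- if (condition == "srm_as_predictor") default_predictor_gamma()
             else default_outcome_gamma()
  structure(list(condition = condition, n_families = as.integer(n_families),
                 reps = as.integer(reps), seed = as.integer(seed),
                 missing = missing, methods = methods, params = params,
                 gamma = gamma),
            class = "srm_sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Flat keys mirror the arguments of [srm_sim_config()]; `gamma` may be
#' given as a 9 x K matrix (list of rows) for the outcome condition.
#'
#' @param path Path to a YAML file.
#' @return An `srm_sim_config` object.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read configuration files",
         call. = FALSE)
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("condition", "n_families", "reps", "seed",
                                  "missing", "methods"))]
  if (!is.null(y$gamma) && identical(y$condition, "srm_as_outcome"))
    args$gamma <- do.call(rbind, y$gamma)
  do.call(srm_sim_config, args)
}

# true coefficient vector per tracked coefficient name
.study_truth <- function(config) {
  if (config$condition == "srm_as_predictor") {
    g <- config$gamma$coef
    nm <- as.vector(t(outer(srm_roles(), c("fam", "act", "par"),
                            function(r, t) paste0("y_", r, ".", t))))
    stats::setNames(as.vector(t(g)), nm)
  } else {
    g <- config$gamma
    K <- ncol(g)
    nm <- as.vector(t(outer(srm_factors(), paste0("z_", seq_len(K)), paste, sep = ".")))
    stats::setNames(as.vector(t(g)), nm)
  }
}

# one replicate -> per-method named vectors of estimates and SEs
.study_replicate <- function(config, seed_r) {
  data <- if (config$condition == "srm_as_predictor")
    generate_predictor_condition(config$n_families, config$params,
                                 config$gamma, seed = seed_r)
  else
    generate_outcome_condition(config$n_families, config$params,
                               config$gamma, seed = seed_r)
  data <- apply_missingness(data, config$missing)
  miss <- family_missing_rate(data)
  truth <- .study_truth(config)
  out <- list()
  fits <- list()
  for (method in config$methods) {
    res <- tryCatch(
      .study_method(config, data, method, fits),
      error = function(e) NULL)
    if (is.null(res)) {
      out[[method]] <- list(converged = FALSE,
                            est = truth * NA_real_, se = truth * NA_real_)
    } else {
      fits <- res$fits
      out[[method]] <- res[c("converged", "est", "se")]
    }
  }
  list(methods = out, missing_rate = miss)
}

.study_method <- function(config, data, method, fits) {
  truth <- .study_truth(config)
  est <- truth * NA_real_
  se <- truth * NA_real_
  if (method == "sem") {
    fit <- suppressMessages(fit_joint_sem(
      data,
      direction = config$condition,
      compute_vcov = TRUE, quiet = TRUE))
    if (!fit$converged) return(list(converged = FALSE, est = est, se = se, fits = fits))
    sc <- structural_coefficients(fit)
    if (config$condition == "srm_as_predictor") {
      nm <- paste0(sc$outcome, ".", sc$term)
    } else {
      nm <- paste0(sc$effect, ".", sc$term)
    }
    keep <- sc$term != "(Intercept)" & nm %in% names(est)
    est[nm[keep]] <- sc$estimate[keep]
    se[nm[keep]] <- sc$se[keep]
    return(list(converged = TRUE, est = est, se = se, fits = fits))
  }
  # factor-score methods
  fs_key <- if (method %in% c("regression_fiml", "bartlett_fiml")) "fiml" else "ml"
  if (method != "anova" && is.null(fits[[fs_key]])) {
    fits[[fs_key]] <- if (fs_key == "fiml")
      fit_srm_fiml(data, compute_vcov = FALSE, quiet = TRUE)
    else
      fit_srm_ml(data, compute_vcov = FALSE, quiet = TRUE)
  }
  if (method != "anova" && !fits[[fs_key]]$converged)
    return(list(converged = FALSE, est = est, se = se, fits = fits))
  scores <- switch(method,
                   anova = anova_scores(data),
                   regression = regression_scores(fits[[fs_key]], data),
                   bartlett_pinv = bartlett_scores(fits[[fs_key]], data, "pinv"),
                   regression_fiml = suppressWarnings(
                     regression_fiml_scores(fits[[fs_key]], data)),
                   bartlett_fiml = bartlett_fiml_scores(fits[[fs_key]], data))
  if (config$condition == "srm_as_predictor") {
    for (r in srm_roles()) {
      fr <- tryCatch(fsr_predictor(scores, data, r, quiet = TRUE),
                     error = function(e) NULL)
      if (is.null(fr)) next
      keep <- fr$term != "(Intercept)"
      nm <- paste0("y_", r, ".", c("fam", "act", "par"))
      est[nm] <- fr$estimate[keep]
      se[nm] <- fr$se_naive[keep]
    }
  } else {
    fr <- fsr_outcome(scores, data, quiet = TRUE)
    keep <- fr$term != "(Intercept)"
    nm <- paste0(fr$effect, ".", fr$term)[keep]
    est[nm] <- fr$estimate[keep]
    se[nm] <- fr$se_naive[keep]
  }
  list(converged = TRUE, est = est, se = se, fits = fits)
}

#' Summarize Monte-Carlo replicate estimates
#'
#' Computes the study's performance metrics per coefficient: the median
#' estimate; the median-bias z-score
#' `(median - truth) / (1.2533 sd / sqrt(R))` (1.2533 is the asymptotic
#' standard-error inflation of the median relative to the mean); the
#' empirical coverage of the Wald 95% confidence interval; and the median
#' absolute deviation (MAD) from the true value.
#'
#' @param estimates R x P matrix of replicate estimates (columns named by
#'   coefficient); non-converged replicates as `NA` rows.
#' @param ses Matching matrix of standard errors.
#' @param truth Named vector of true values.
#' @param min_reps Minimum converged replicates required per coefficient.
#' @return A data frame with columns `coefficient`, `truth`, `median_est`,
#'   `bias_z`, `coverage`, `mad`, `n_converged`.
#' @export
summarize_replicates <- function(estimates, ses, truth, min_reps = 30L) {
  estimates <- as.matrix(estimates)
  ses <- as.matrix(ses)
  out <- lapply(colnames(estimates), function(cn) {
    e <- estimates[, cn]
    s <- ses[, cn]
    ok <- !is.na(e)
    R <- sum(ok)
    if (R < min_reps)
      return(data.frame(coefficient = cn, truth = truth[[cn]],
                        median_est = NA_real_, bias_z = NA_real_,
                        coverage = NA_real_, mad = NA_real_, n_converged = R))
    med <- stats::median(e[ok])
    se_med <- 1.2533 * stats::sd(e[ok]) / sqrt(R)
    bias_z <- if (se_med == 0) {
      if (med == truth[[cn]]) 0 else sign(med - truth[[cn]]) * Inf
    } else (med - truth[[cn]]) / se_med
    cov_ok <- ok & !is.na(s)
    covg <- mean(abs(estimates[cov_ok, cn] - truth[[cn]]) <=
                   1.96 * ses[cov_ok, cn])
    data.frame(coefficient = cn, truth = truth[[cn]], median_est = med,
               bias_z = bias_z, coverage = covg,
               mad = stats::median(abs(e[ok] - truth[[cn]])), n_converged = R)
  })
  do.call(rbind, out)
}

#' Run a Monte-Carlo comparison study
#'
#' For each replicate: generate data under the configured condition, apply
#' the missingness mechanism, run every configured method (joint SEM
#' and/or two-step factor-score regressions), and collect the structural
#' coefficient estimates with their standard errors.  Replicates on which
#' a method does not converge are excluded from that method's summaries
#' and counted.  With a fixed configuration and seed the output is
#' bit-reproducible.
#'
#' @param config An [srm_sim_config] object.
#' @param progress Print a dot every 10 replicates.
#' @param min_reps Minimum converged replicates a cell needs before it is
#'   summarized (passed to [summarize_replicates()]).
#' @return A data frame of class `srm_sim_summary` with one row per
#'   method x coefficient: the [summarize_replicates()] metrics plus
#'   `convergence_rate` and the mean family-level `missing_rate`.  The raw
#'   replicate estimates are attached as attribute `"replicates"`.
#' @export
run_study <- function(config, progress = FALSE, min_reps = 30L) {
  stopifnot(inherits(config, "srm_sim_config"))
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$reps)
  truth <- .study_truth(config)
  P <- length(truth)
  est <- ses <- lapply(config$methods, function(m)
    matrix(NA_real_, config$reps, P, dimnames = list(NULL, names(truth))))
  names(est) <- names(ses) <- config$methods
  conv <- matrix(FALSE, config$reps, length(config$methods),
                 dimnames = list(NULL, config$methods))
  missr <- numeric(config$reps)
  for (r in seq_len(config$reps)) {
    rep_r <- .study_replicate(config, rep_seeds[r])
    missr[r] <- rep_r$missing_rate
    for (m in config$methods) {
      conv[r, m] <- rep_r$methods[[m]]$converged
      if (conv[r, m]) {
        est[[m]][r, ] <- rep_r$methods[[m]]$est[names(truth)]
        ses[[m]][r, ] <- rep_r$methods[[m]]$se[names(truth)]
      }
    }
    if (progress && r %% 10L == 0L) cat(".")
  }
  if (progress) cat("\n")
  out <- do.call(rbind, lapply(config$methods, function(m) {
    s <- summarize_replicates(est[[m]], ses[[m]], truth, min_reps = min_reps)
    data.frame(method = m, s, convergence_rate = mean(conv[, m]),
               missing_rate = mean(missr), row.names = NULL)
  }))
  structure(out, class = c("srm_sim_summary", "data.frame"), config = config,
            replicates = list(estimates = est, ses = ses, converged = conv))
}

#' Write a simulation summary to CSV
#'
#' @param summary An `srm_sim_summary` from [run_study()].
#' @param path Output path.
#' @export
write_summary_csv <- function(summary, path) {
  utils::write.csv(as.data.frame(summary), path, row.names = FALSE, na = "")
  invisible(path)
}
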