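# shared fixtures, all built in code

# single-factor toy model: q indicators with unit loadings, factor
# variance psi, iid error variance th -- full-rank loading matrix
toy_model <- function(q = 3L, psi = 0.8, th = 0.5, mu = NULL) {
  list(loading = matrix(1, q, 1L),
       factor_cov = matrix(psi, 1L, 1L),
       resid_cov = diag(th, q),
       mean_vector = if (is.null(mu)) numeric(q) else mu)
}

# a structurally rich but valid SRM parameter set for identity checks
rich_params <- function() {
  srm_parameters(fam_var = 0.8,
                 act_var = c(M = 1.2, F = 0.9, T = 1.1, S = 1.0),
                 par_var = c(M = 0.6, F = 0.4, T = 0.7, S = 0.5),
                 gen_recip = c(M = 0.1, F = -0.1, T = 0.05, S = -0.02),
                 resid_var = seq(1.2, 2.3, by = 0.1),
                 dyad_recip = c(0.05, -0.03, 0.02, 0.04, -0.02, 0.01),
                 mean_fam = 2,
                 mean_act = c(0.3, -0.1, -0.1, -0.1),
                 mean_par = c(-0.2, 0.2, 0.1, -0.1))
}

# random valid SRM parameter set (PD factor and residual covariances)
random_params <- function() {
  av <- runif(4, 0.6, 1.4)
  pv <- runif(4, 0.3, 0.9)
  srm_parameters(fam_var = runif(1, 0.5, 1.5),
                 act_var = av, par_var = pv,
                 gen_recip = runif(4, -0.4, 0.4) * sqrt(av * pv),
                 resid_var = runif(12, 0.8, 2.5),
                 dyad_recip = runif(6, -0.3, 0.3))
}

# free covariance-parameter vector of a parameter set (truth for recovery)
true_theta <- function(p) famsrm:::.theta_from_params(p)

# the 4 x 4 round-robin table with one nonzero cell, as a 12-vector
one_cell_table <- function(value = 8, cell = "MF") {
  x <- stats::setNames(numeric(12L), srm_dyads())
  x[cell] <- value
  x
}
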