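#' Role, dyad and factor conventions of the four-member family SRM
#'
#' The package fixes a canonical ordering for the four family roles
#' (M = mother, F = father, T = target adolescent, S = sibling), the twelve
#' ordered actor-partner dyads (actor-major order), and the nine latent SRM
#' effects (one family effect, four actor effects, four partner effects).
#' All matrices, score vectors and data columns in the package follow these
#' orderings.
#'
#' @return `srm_roles()` returns the four role labels; `srm_dyads()` the
#'   twelve ordered dyad labels (`"MF"` means mother rating father);
#'   `srm_factors()` the nine latent-effect labels; `srm_dyad_pairs()` the
#'   six unordered reciprocal dyad pairs (`"M/F"` couples `"MF"` with
#'   `"FM"`).
#' @examples
#' srm_dyads()
#' srm_factors()
#' @export
srm_roles <- function() c("M", "F", "T", "S")

#' @rdname srm_roles
#' @export
srm_dyads <- function() {
  r <- srm_roles()
  unlist(lapply(r, function(i) paste0(i, r[r != i])), use.names = FALSE)
}

#' @rdname srm_roles
#' @export
srm_factors <- function() {
  c("Fam", paste0("Act_", srm_roles()), paste0("Par_", srm_roles()))
}

#' @rdname srm_roles
#' @export
srm_dyad_pairs <- function() c("M/F", "M/T", "M/S", "F/T", "F/S", "T/S")

# row indices into srm_dyads() of the two members of each reciprocal pair,
# in the order of srm_dyad_pairs()
.pair_index <- function() {
  dy <- srm_dyads()
  t(vapply(srm_dyad_pairs(), function(p) {
    ij <- strsplit(p, "/", fixed = TRUE)[[1L]]
    c(match(paste0(ij[1L], ij[2L]), dy), match(paste0(ij[2L], ij[1L]), dy))
  }, numeric(2L)))
}

.actor_of <- function(dyad) substr(dyad, 1L, 1L)
.partner_of <- function(dyad) substr(dyad, 2L, 2L)

#' Loading matrix of the family SRM
#'
#' Builds the fixed 12 x 9 loading matrix of the four-member SRM: the row
#' for dyad (i, j) has unit loadings on the family effect, the actor effect
#' of role i and the partner effect of role j, and zeros elsewhere.  The
#' matrix has rank 7: the family column equals both the sum of the four
#' actor columns and the sum of the four partner columns, so its null space
#' is two-dimensional.
#'
#' @return A 12 x 9 numeric matrix with dyads as rows and SRM effects as
#'   columns.
#' @examples
#' L <- srm_loading_matrix()
#' rowSums(L)            # every dyad loads on exactly three effects
#' qr(L)$rank            # 7
#' @export
srm_loading_matrix <- function() {
  dy <- srm_dyads()
  L <- matrix(0, 12L, 9L, dimnames = list(dy, srm_factors()))
  L[, "Fam"] <- 1
  L[cbind(seq_len(12L), match(paste0("Act_", .actor_of(dy)), colnames(L)))] <- 1
  L[cbind(seq_len(12L), match(paste0("Par_", .partner_of(dy)), colnames(L)))] <- 1
  L
}

# Moore-Penrose pseudo-inverse; singular values below rtol * largest are
# treated as zero so the structural rank deficit (7 of 9) is detected
# stably even for estimated residual covariances.
.pinv <- function(A, rtol = 1e-10) {
  s <- svd(A)
  keep <- s$d > rtol * max(s$d[1L], .Machine$double.xmin)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

.mat_rank <- function(A, rtol = 1e-10) {
  d <- svd(A, nu = 0, nv = 0)$d
  sum(d > rtol * max(d[1L], .Machine$double.xmin))
}

.is_pd <- function(A, tol = 1e-10) {
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol
}
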