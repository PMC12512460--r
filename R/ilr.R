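# Isometric log-ratio machinery shared by the compositional-PCA covariate
# step and the cohort generator. The basis is fixed by the order of the
# part labels (orthonormalized Helmert contrasts), so results are
# reproducible for a given cell-type ordering.

#' Orthonormal ilr basis for a D-part composition
#'
#' Columns are orthonormal, orthogonal to the constant vector, and fixed by
#' the part order, so the same labels always give the same coordinates.
#'
#' @param d Number of parts (>= 2).
#' @return A \code{d x (d-1)} matrix whose columns form an ilr basis.
#' @export
ilr_basis <- function(d) {
  stopifnot(d >= 2)
  h <- stats::contr.helmert(d)
  sweep(h, 2, sqrt(colSums(h^2)), "/")
}

#' Isometric log-ratio transform
#'
#' Maps rows of a composition matrix (parts summing to 1, all positive) to
#' D-1 unconstrained coordinates.
#'
#' @param x Matrix (or vector) of compositions, parts in columns.
#' @param basis Optional basis from \code{ilr_basis}; defaults to the
#'   Helmert basis for \code{ncol(x)} parts.
#' @return Matrix of ilr coordinates, one row per composition.
#' @export
ilr <- function(x, basis = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (any(x <= 0)) stop("ilr requires strictly positive parts; apply zero replacement first")
  if (is.null(basis)) basis <- ilr_basis(ncol(x))
  log(x) %*% basis
}

#' Inverse isometric log-ratio transform
#'
#' @param z Matrix (or vector) of ilr coordinates, one row per composition.
#' @param basis Basis used for the forward transform.
#' @return Matrix of compositions with rows summing to 1.
#' @export
ilr_inv <- function(z, basis = NULL) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (is.null(basis)) basis <- ilr_basis(ncol(z) + 1L)
  clr <- z %*% t(basis)
  e <- exp(clr - apply(clr, 1, max))
  sweep(e, 1, rowSums(e), "/")
}
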