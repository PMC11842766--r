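# Representational dissimilarity matrices: the pipeline's common currency.
# Correlation-distance RDMs from condition x voxel patterns, subject
# averaging, and the fixed upper-triangle vectorization used by all
# second-level analyses.

#' Correlation-distance RDM from a pattern matrix
#'
#' `d(i, j) = 1 - r(i, j)` where `r` is the Pearson correlation between the
#' voxel patterns of conditions `i` and `j`. Entries lie in `[0, 2]`.
#'
#' @param P Condition x voxel numeric matrix (>= 3 conditions, >= 2 voxels);
#'   row names, when present, become RDM labels.
#' @return A symmetric zero-diagonal RDM matrix.
#' @export
compute_rdm <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) < 3L || ncol(P) < 2L)
    stop("pattern matrix needs >= 3 conditions and >= 2 voxels")
  if (!all(is.finite(P))) stop("pattern matrix contains non-finite values")
  v <- apply(P, 1L, stats::var)
  if (any(v == 0))
    stop("zero-variance condition pattern (degenerate ROI/condition)")
  d <- 1 - stats::cor(t(P))
  diag(d) <- 0
  d
}

#' Element-wise mean of RDMs
#'
#' Averages a list of RDMs sharing condition labels and order, e.g. to form
#' group-average RDMs across subjects.
#'
#' @param rdms Non-empty list of equally-labelled RDM matrices.
#' @return The element-wise mean RDM.
#' @export
average_rdms <- function(rdms) {
  if (length(rdms) == 0L) stop("empty RDM list")
  lab <- rownames(rdms[[1]])
  for (r in rdms) {
    if (!identical(dim(r), dim(rdms[[1]])) || !identical(rownames(r), lab))
      stop("RDM labels/dimensions mismatch")
  }
  Reduce(`+`, rdms) / length(rdms)
}

#' Upper-triangle vectorization of an RDM
#'
#' Extracts the strictly-upper entries in the project-wide fixed order:
#' row-major over pairs `(i, j)` with `i < j`, i.e. (1,2), (1,3), ...,
#' (1,n), (2,3), ... This ordering is used consistently by every second-level
#' correlation in the package.
#'
#' @param R A square symmetric matrix.
#' @return Numeric vector of length `n(n-1)/2`.
#' @export
upper_tri <- function(R) {
  R <- as.matrix(R)
  n <- nrow(R)
  t(R)[lower.tri(R)]   # transpose gives row-major (i < j) order
}

#' Rebuild a symmetric zero-diagonal matrix from its upper triangle
#'
#' Inverse of [upper_tri()].
#'
#' @param v Vector of length `n(n-1)/2` in row-major `(i < j)` order.
#' @param labels Optional condition labels.
#' @return The reconstructed symmetric matrix with zero diagonal.
#' @export
rdm_from_upper <- function(v, labels = NULL) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(n - round(n)) > 1e-9)
    stop("vector length is not n(n-1)/2 for integer n")
  n <- as.integer(round(n))
  L <- matrix(0, n, n)
  # column-major lower triangle of L == row-major upper triangle of t(L)
  L[lower.tri(L)] <- v
  R <- L + t(L)
  if (!is.null(labels)) dimnames(R) <- list(labels, labels)
  R
}

# Internal validation used by IO and second-level stages.
.check_rdm <- function(R, tol = 1e-8) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) stop("RDM must be square")
  if (max(abs(R - t(R))) > tol) stop("RDM must be symmetric")
  if (max(abs(diag(R))) > tol) stop("RDM diagonal must be zero")
  invisible(TRUE)
}
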