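#' Orthonormal eigendecomposition of a graph Laplacian
#'
#' Eigenvalues are sorted in decreasing order (0 first under the
#' semi-negative-definite convention).  On a connected graph the 0-mode is
#' one-dimensional and its eigenvector is returned as the positive constant
#' vector \eqn{\mathbf{1}/\sqrt{N}}.
#'
#' @param L symmetric Laplacian matrix.
#' @return A list of class `graph_basis`: `values` (decreasing), `vectors`
#'   (orthonormal columns, aligned with `values`).
#' @export
eigendecompose <- function(L) {
  if (!isSymmetric(unname(as.matrix(L)), tol = 1e-10))
    stop("eigendecompose: matrix must be symmetric", call. = FALSE)
  e <- eigen(as.matrix(L), symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  val <- e$values[ord]
  vec <- e$vectors[, ord, drop = FALSE]
  # fix the sign of each vector (largest-magnitude entry positive) so that
  # the constant 0-mode of a connected graph comes out as +1/sqrt(N)
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  structure(list(values = val, vectors = vec), class = "graph_basis")
}

#' Graph Fourier coefficients of a node field
#'
#' Projects a node field onto the Laplacian eigenbasis:
#' \eqn{k_i = \langle x, \gamma_i \rangle}, so that
#' \eqn{x = \sum_i k_i \gamma_i} exactly and Parseval's identity
#' \eqn{\sum_i k_i^2 = \|x\|^2} holds.  On a connected graph a spatially
#' homogeneous field has only the 0-eigenvalue coefficient non-zero.
#'
#' @param field numeric vector of length N.
#' @param basis a `graph_basis` from [eigendecompose].
#' @return Numeric vector of N coefficients, aligned with `basis$values`.
#' @export
fourier_coefficients <- function(field, basis) {
  if (length(field) != nrow(basis$vectors))
    stop("field length does not match the basis dimension", call. = FALSE)
  as.vector(crossprod(basis$vectors, field))
}

#' Spectral scatter points of a node field
#'
#' The display representation of the graph Fourier transform: one point per
#' coefficient with `|k| > floor`, abscissa the negated eigenvalue
#' (non-negative) and ordinate \eqn{\log_2 |k|}.  The default floor of
#' \eqn{2^{-18}} suppresses numerically negligible modes.
#'
#' @inheritParams fourier_coefficients
#' @param floor positive magnitude cutoff.
#' @return Data frame with columns `eigenvalue`, `minus_eigenvalue`,
#'   `coefficient`, `log2_abs_coefficient`.
#' @export
scatter_points <- function(field, basis, floor = 2^-18) {
  if (floor <= 0) stop("floor must be positive", call. = FALSE)
  k <- fourier_coefficients(field, basis)
  keep <- abs(k) > floor
  data.frame(eigenvalue = basis$values[keep],
             minus_eigenvalue = -basis$values[keep],
             coefficient = k[keep],
             log2_abs_coefficient = log2(abs(k[keep])))
}

#' Per-eigenvalue spectral energy of a node field
#'
#' Sums squared Fourier coefficients over (numerically) equal eigenvalues.
#' Lattice Laplacians have high-multiplicity eigenspaces in which
#' individual eigenvectors are solver-dependent; the summed energy per
#' eigenvalue is rotation-invariant and therefore the right quantity for
#' quantitative statements.
#'
#' @inheritParams fourier_coefficients
#' @param digits rounding used to group equal eigenvalues.
#' @return Data frame with columns `eigenvalue` and `energy`, sorted with
#'   the 0-eigenvalue first.
#' @export
spectral_energy <- function(field, basis, digits = 8) {
  k <- fourier_coefficients(field, basis)
  ev <- round(basis$values, digits)
  agg <- tapply(k^2, ev, sum)
  out <- data.frame(eigenvalue = as.numeric(names(agg)),
                    energy = as.numeric(agg))
  out[order(out$eigenvalue, decreasing = TRUE), , drop = FALSE]
}
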