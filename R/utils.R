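#' Principal angles between two subspaces
#'
#' Computes the principal angles (radians) between the column spaces of
#' two matrices with equal row dimension, via the singular values of the
#' product of their orthonormal bases. Useful for comparing fitted
#' projections whose individual vectors are only defined up to rotation
#' within degenerate eigenspaces.
#'
#' @param U,V Numeric matrices with the same number of rows.
#' @return Numeric vector of angles in radians, length
#'   \code{min(ncol(U), ncol(V))}, non-decreasing.
#' @export
principal_angles <- function(U, V) {
  Qu <- qr.Q(qr(as.matrix(U)))
  Qv <- qr.Q(qr(as.matrix(V)))
  s <- svd(crossprod(Qu, Qv))$d
  acos(pmin(pmax(s, -1), 1))
}
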