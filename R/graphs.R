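#' Build a k-nearest-neighbor heat-kernel affinity graph
#'
#' Connects each point to its k nearest neighbors (Euclidean metric) and
#' weights edge (i, j) by the heat kernel \code{exp(-||p_i - p_j||^2 / t)}.
#' The directed kNN relation is OR-symmetrized: an edge exists if i is
#' among the k nearest neighbors of j or vice versa, which makes the
#' affinity matrix symmetric with at least k nonzeros per row. Self-edges
#' are excluded (zero diagonal). In \code{mode = "molecular"} the points
#' are gene-expression profiles; in \code{mode = "spatial"} they are the
#' 2D spot coordinates — the construction is identical, only the feature
#' space differs.
#'
#' @param points Numeric matrix, one point per row (spots x features).
#' @param k Neighbor count, \code{1 <= k < n}.
#' @param t Heat-kernel bandwidth in squared-distance units, or
#'   \code{"auto"} to use the median squared distance to the k-th nearest
#'   neighbor (reported via \code{message}).
#' @param mode \code{"molecular"} or \code{"spatial"}; recorded on the
#'   graph object.
#' @return An object of class \code{affinity_graph}: list with the n x n
#'   symmetric weight matrix \code{S}, and \code{k}, \code{t}, \code{mode}.
#' @export
build_knn_affinity <- function(points, k, t = "auto",
                               mode = c("molecular", "spatial")) {
  mode <- match.arg(mode)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop("need at least 2 points")
  if (!all(is.finite(points))) stop("points must be finite")
  if (k < 1) stop("k must be >= 1")
  if (k >= n) stop("k (", k, ") must be smaller than the number of points (",
                   n, ")")

  D2 <- .pairwise_sq_dist(points)

  # k nearest neighbors per column, self excluded, distance ties broken by
  # lowest index so the graph is a deterministic function of the input
  nn_idx <- matrix(0L, k, n)
  kth_d2 <- numeric(n)
  for (j in seq_len(n)) {
    d <- D2[, j]
    d[j] <- Inf
    ord <- order(d, seq_len(n))[seq_len(k)]
    nn_idx[, j] <- ord
    kth_d2[j] <- d[ord[k]]
  }

  if (identical(t, "auto")) {
    t <- stats::median(kth_d2)
    if (t <= 0) t <- 1   # duplicate-heavy input: any t gives weight 1 edges
    message(sprintf("heat-kernel bandwidth t resolved to %.6g", t))
  }
  if (!is.numeric(t) || t <= 0) stop("t must be a positive number or 'auto'")

  A <- matrix(0, n, n)   # directed: A[i, j] > 0 iff i is a kNN of j
  for (j in seq_len(n)) A[nn_idx[, j], j] <- exp(-D2[nn_idx[, j], j] / t)
  S <- pmax(A, t(A))
  diag(S) <- 0

  structure(list(S = S, k = as.integer(k), t = t, mode = mode),
            class = "affinity_graph")
}

.pairwise_sq_dist <- function(points) {
  sq <- rowSums(points^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(points)
  D2[D2 < 0] <- 0   # guard tiny negative values from cancellation
  D2
}

#' @export
print.affinity_graph <- function(x, ...) {
  cat(sprintf("affinity_graph: %d nodes, k = %d, t = %.6g, mode = %s\n",
              nrow(x$S), x$k, x$t, x$mode))
  invisible(x)
}

#' Symmetric normalized graph Laplacian
#'
#' Computes \code{Lbar = D^{-1/2} (D - S) D^{-1/2}} where \code{D} is the
#' diagonal degree matrix of the affinity matrix \code{S}. Eigenvalues of
#' \code{Lbar} lie in [0, 2]. Rows and columns belonging to zero-degree
#' nodes are set to zero (with a warning) rather than erroring, so spot
#' indices stay aligned with the data matrix.
#'
#' @param graph An \code{affinity_graph}, or a symmetric nonnegative
#'   matrix.
#' @return Symmetric n x n matrix.
#' @export
normalized_laplacian <- function(graph) {
  S <- if (inherits(graph, "affinity_graph")) graph$S else as.matrix(graph)
  if (any(S < 0)) stop("affinity matrix must be nonnegative")
  if (max(abs(S - t(S))) > 1e-12) stop("affinity matrix must be symmetric")
  deg <- rowSums(S)
  zero <- deg == 0
  if (any(zero))
    warning(sum(zero), " zero-degree node(s); their Laplacian rows/columns ",
            "are set to 0")
  dinv <- ifelse(zero, 0, 1 / sqrt(deg))
  Lbar <- -S * tcrossprod(dinv)
  diag(Lbar) <- ifelse(zero, 0, 1)
  (Lbar + t(Lbar)) / 2
}

#' Graph Laplacian smoothing filter
#'
#' Builds the filter \code{H = I - mu * Lbar}. With \code{mu = 0} the
#' filter is the identity (no smoothing; the contrastive model then
#' reduces to contrastive PCA); larger \code{mu} damps high-frequency
#' graph components more strongly. Since the eigenvalues of \code{Lbar}
#' lie in [0, 2], those of \code{H} lie in [1 - 2 mu, 1].
#'
#' @param Lbar Symmetric normalized Laplacian matrix.
#' @param mu Smoothing weight in [0, 1].
#' @return An object of class \code{laplacian_filter}: list with the
#'   matrix \code{H}, \code{mu}, and \code{Lbar}.
#' @export
laplacian_filter <- function(Lbar, mu) {
  Lbar <- as.matrix(Lbar)
  if (!is.numeric(mu) || length(mu) != 1 || mu < 0 || mu > 1)
    stop("mu must lie in [0, 1]")
  if (max(abs(Lbar - t(Lbar))) > 1e-10) stop("Lbar must be symmetric")
  H <- diag(nrow(Lbar)) - mu * Lbar
  structure(list(H = H, mu = mu, Lbar = Lbar), class = "laplacian_filter")
}

#' @export
print.laplacian_filter <- function(x, ...) {
  cat(sprintf("laplacian_filter: %d nodes, mu = %.3g\n", nrow(x$H), x$mu))
  invisible(x)
}

# Convenience: affinity graph -> filter in one step.
graph_filter <- function(graph, mu) laplacian_filter(normalized_laplacian(graph), mu)
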