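#' Cluster an embedding into spatial domains
#'
#' Groups spots by their contrastive components, either with k-means
#' (\code{method = "kmeans"}, fixed seed and 10 restarts) or with Louvain
#' community detection on a kNN graph of the embedding
#' (\code{method = "graph_louvain"}). Cluster indices are relabeled by
#' decreasing cluster size (ties by first occurrence), so the output does
#' not depend on the algorithm's internal label permutation. Clustering
#' is performed directly on the components; any UMAP view is a separate,
#' purely visual step.
#'
#' @param Z Numeric matrix, spots x p, rownames taken as spot ids.
#' @param method \code{"kmeans"} or \code{"graph_louvain"}.
#' @param n_clusters Number of clusters (k-means).
#' @param resolution Louvain resolution parameter (default 1).
#' @param knn Neighborhood size for the Louvain graph (default 15).
#' @param seed Integer seed.
#' @return An object of class \code{domain_assignment}: list with
#'   \code{spot_ids}, \code{labels} (integers from 0, 0 the largest
#'   domain), \code{method}, \code{params}, \code{seed}.
#' @export
cluster_embedding <- function(Z, method = c("kmeans", "graph_louvain"),
                              n_clusters = NULL, resolution = 1, knn = 15,
                              seed = 1) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  if (!all(is.finite(Z))) stop("embedding must be finite")
  spot_ids <- rownames(Z)
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(Z)))
  set.seed(seed)
  if (method == "kmeans") {
    if (is.null(n_clusters)) stop("n_clusters is required for kmeans")
    if (n_clusters > nrow(Z)) stop("n_clusters exceeds the number of spots")
    raw <- stats::kmeans(Z, centers = n_clusters, nstart = 10,
                         iter.max = 100)$cluster
    params <- list(n_clusters = n_clusters)
  } else {
    k_eff <- min(knn, nrow(Z) - 1)
    g <- build_knn_affinity(Z, k = k_eff, t = "auto", mode = "molecular")
    ig <- igraph::graph_from_adjacency_matrix(g$S, mode = "undirected",
                                              weighted = TRUE)
    raw <- igraph::cluster_louvain(ig, resolution = resolution)$membership
    params <- list(resolution = resolution, knn = k_eff)
  }
  sizes <- table(raw)
  new_order <- names(sizes)[order(-as.integer(sizes), seq_along(sizes))]
  labels <- match(as.character(raw), new_order) - 1L
  structure(list(spot_ids = spot_ids, labels = labels, method = method,
                 params = params, seed = as.integer(seed)),
            class = "domain_assignment")
}

#' @export
print.domain_assignment <- function(x, ...) {
  cat(sprintf("domain_assignment: %d spots in %d domains (%s)\n",
              length(x$labels), length(unique(x$labels)), x$method))
  invisible(x)
}

#' Write a domain table
#'
#' Exports spot ids and domain labels (optionally with the embedding
#' columns) as a TSV consumable by downstream differential-expression or
#' trajectory tools.
#'
#' @param assignment A \code{domain_assignment}.
#' @param path Output path.
#' @param embedding Optional spots x p matrix to append, matched by row
#'   order.
#' @return Invisibly, \code{path}.
#' @export
write_domains <- function(assignment, path, embedding = NULL) {
  stopifnot(inherits(assignment, "domain_assignment"))
  df <- data.frame(spot_id = assignment$spot_ids,
                   domain = assignment$labels,
                   stringsAsFactors = FALSE)
  if (!is.null(embedding)) {
    embedding <- as.matrix(embedding)
    if (nrow(embedding) != length(assignment$spot_ids))
      stop("embedding rows must match the assignment")
    colnames(embedding) <- paste0("CC", seq_len(ncol(embedding)))
    df <- cbind(df, embedding)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
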