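#' Graph-filtered gene scatter matrix
#'
#' Computes \code{X H X^T} for a genes-by-spots matrix \code{X} and a
#' Laplacian filter \code{H}, the building block of the contrastive
#' objective. With \code{H = I} this is the plain (unnormalized) gene
#' scatter. The result is symmetrized as \code{(M + M^T)/2} to remove
#' floating-point asymmetry.
#'
#' @param X Numeric matrix, genes x spots, gene-centered.
#' @param H A \code{laplacian_filter} or a plain symmetric matrix of
#'   matching spot dimension.
#' @return Symmetric d x d matrix.
#' @export
filtered_scatter <- function(X, H) {
  Hm <- if (inherits(H, "laplacian_filter")) H$H else as.matrix(H)
  X <- as.matrix(X)
  if (ncol(X) != nrow(Hm))
    stop("spot dimension mismatch: ncol(X) = ", ncol(X),
         ", filter is ", nrow(Hm), " x ", ncol(Hm))
  M <- X %*% Hm %*% t(X)
  (M + t(M)) / 2
}

# Symmetric eigendecomposition of Bt - eta * Bb with deterministic sign
# fixing: the entry of largest absolute value in each eigenvector is made
# positive (ties broken by lowest index, which.max's behavior).
.contrastive_eigen <- function(Bt, Bb, eta) {
  M <- Bt - eta * Bb
  M <- (M + t(M)) / 2
  if (!all(is.finite(M))) stop("non-finite entries in contrast matrix")
  e <- eigen(M, symmetric = TRUE)   # values in decreasing order
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(values = e$values, vectors = V, M = M)
}

#' Fit a contrastive spatial feature representation
#'
#' Learns an orthonormal projection \code{W} (genes x p) whose columns
#' maximize the graph-filtered variance of the target slice minus
#' \code{eta} times that of the background slice. Each slice gets a
#' k-nearest-neighbor heat-kernel affinity graph (on expression profiles
#' for \code{graph_mode = "molecular"}, on spot coordinates for
#' \code{"spatial"}), converted to a smoothing filter
#' \code{H = I - mu * Lbar}. \code{W} then solves the symmetric
#' eigenproblem
#' \deqn{(X_t H_t X_t^T - \eta\, X_b H_b X_b^T)\, w = \lambda w,}
#' keeping the eigenvectors with the p algebraically largest eigenvalues.
#' With \code{mu1 = mu2 = 0} this is exactly contrastive PCA; with
#' \code{eta = 0} it is a graph-smoothed PCA of the target alone.
#'
#' Components with negative eigenvalues mostly reflect background-enriched
#' structure; they are excluded by default and retained when
#' \code{include_negative = TRUE}.
#'
#' @param background,target Standardized \code{spatial_dataset} objects
#'   with identical gene namespaces (see \code{\link{align_genes}},
#'   \code{\link{standardize_genes}}). Plain spots-by-genes matrices are
#'   accepted and wrapped (molecular mode only).
#' @param eta Contrastive trade-off parameter, \code{>= 0}. Default 1.
#' @param mu1,mu2 Smoothing weights in [0, 1] for the background and
#'   target filters. Default 0.5.
#' @param k Neighbor count for graph construction. Default 15 for
#'   molecular graphs, 6 for spatial (the Visium hex neighborhood).
#' @param t Heat-kernel bandwidth or \code{"auto"} (per-graph median
#'   squared k-th-neighbor distance).
#' @param p Number of components requested. Default 30.
#' @param graph_mode \code{"molecular"} or \code{"spatial"}.
#' @param include_negative Keep components with eigenvalue <= 0 among the
#'   top p. Default \code{FALSE}.
#' @return An object of class \code{cocost_model}: list with \code{W}
#'   (genes x p, orthonormal columns), \code{eigenvalues} (one per kept
#'   component, non-increasing), \code{spectrum} (all d eigenvalues),
#'   \code{gene_ids}, and the resolved hyperparameters (\code{eta},
#'   \code{mu1}, \code{mu2}, \code{k}, \code{t_b}, \code{t_t},
#'   \code{graph_mode}).
#' @export
cocost <- function(background, target, eta = 1, mu1 = 0.5, mu2 = 0.5,
                   k = NULL, t = "auto", p = 30,
                   graph_mode = c("molecular", "spatial"),
                   include_negative = FALSE) {
  graph_mode <- match.arg(graph_mode)
  background <- .as_standardized(background, "background")
  target <- .as_standardized(target, "target")
  if (!identical(background$gene_ids, target$gene_ids))
    stop("gene namespaces differ; run align_genes() first")
  d <- n_genes(target)
  if (p > d) stop("p (", p, ") exceeds gene count (", d, ")")
  if (eta < 0) stop("eta must be >= 0")
  if (is.null(k)) k <- if (graph_mode == "molecular") 15L else 6L

  fb <- .slice_filter(background, graph_mode, k, t, mu1)
  ft <- .slice_filter(target, graph_mode, k, t, mu2)

  Xb <- t(expr_matrix(background))   # genes x spots
  Xt <- t(expr_matrix(target))
  Bb <- filtered_scatter(Xb, fb$H)
  Bt <- filtered_scatter(Xt, ft$H)
  ce <- .contrastive_eigen(Bt, Bb, eta)

  keep <- seq_len(p)
  if (!include_negative) keep <- keep[ce$values[keep] > 1e-10]
  W <- ce$vectors[, keep, drop = FALSE]
  rownames(W) <- target$gene_ids
  colnames(W) <- if (length(keep)) paste0("CC", seq_along(keep)) else NULL

  structure(list(W = W, eigenvalues = ce$values[keep],
                 spectrum = ce$values, gene_ids = target$gene_ids,
                 eta = eta, mu1 = mu1, mu2 = mu2, k = as.integer(k),
                 t_b = fb$t, t_t = ft$t, graph_mode = graph_mode,
                 p_requested = as.integer(p)),
            class = "cocost_model")
}

.as_standardized <- function(x, arg) {
  if (is.matrix(x) || is.data.frame(x)) {
    x <- spatial_dataset(as.matrix(x), layer = "standardized")
  }
  stopifnot_dataset(x, arg)
  if (x$layer != "standardized")
    stop("'", arg, "' must be standardized (layer is '", x$layer, "'); ",
         "run standardize_genes() first")
  x
}

.slice_graph <- function(ds, graph_mode, k, t) {
  if (graph_mode == "spatial") {
    if (is.null(ds$coords))
      stop("spatial graph mode requires spot coordinates")
    build_knn_affinity(ds$coords, k = k, t = t, mode = "spatial")
  } else {
    build_knn_affinity(expr_matrix(ds), k = k, t = t, mode = "molecular")
  }
}

# Filter for one slice; mu = 0 is the identity filter (the cPCA limit),
# in which case no graph is needed.
.slice_filter <- function(ds, graph_mode, k, t, mu) {
  if (mu == 0)
    return(list(H = diag(n_spots(ds)), t = NA_real_))
  g <- .slice_graph(ds, graph_mode, k, t)
  list(H = graph_filter(g, mu)$H, t = g$t)
}

#' @export
print.cocost_model <- function(x, ...) {
  cat(sprintf(paste0("cocost_model: %d genes -> %d components ",
                     "(eta = %.3g, mu1 = %.3g, mu2 = %.3g, k = %d, %s)\n"),
              length(x$gene_ids), ncol(x$W), x$eta, x$mu1, x$mu2, x$k,
              x$graph_mode))
  if (length(x$eigenvalues))
    cat("  leading eigenvalues:",
        paste(sprintf("%.4g", utils::head(x$eigenvalues, 5)),
              collapse = ", "), "\n")
  invisible(x)
}

#' Project a slice onto the contrastive components
#'
#' Computes \code{Z = X W} for a standardized slice, after restricting and
#' reordering its genes to the model's gene namespace. The slice should be
#' standardized with its own per-gene statistics.
#'
#' @param model A \code{cocost_model}.
#' @param ds A standardized \code{spatial_dataset} (or spots-by-genes
#'   matrix with column names) covering all model genes.
#' @param scale \code{"none"} returns the raw projection scores;
#'   \code{"eigenvalue"} multiplies component j by its eigenvalue share
#'   \code{lambda_j / lambda_1}, so that a component's scale reflects how
#'   much target-specific (contrastive) variance it carries rather than
#'   its total variance in the slice. The scaled form is the recommended
#'   input to clustering: components dominated by residual shared
#'   structure have small contrastive eigenvalues and are damped.
#' @return Numeric matrix, spots x p, rownames the spot ids and columns
#'   \code{CC1..CCp}.
#' @export
cocost_transform <- function(model, ds, scale = c("none", "eigenvalue")) {
  stopifnot(inherits(model, "cocost_model"))
  scale <- match.arg(scale)
  ds <- .as_standardized(ds, "ds")
  X <- .match_model_genes(expr_matrix(ds), model$gene_ids)
  Z <- X %*% model$W
  if (scale == "eigenvalue" && ncol(Z) > 0) {
    ev <- pmax(model$eigenvalues, 0)
    if (ev[1] > 0) Z <- sweep(Z, 2, ev / ev[1], "*")
  }
  rownames(Z) <- ds$spot_ids
  Z
}

.match_model_genes <- function(X, gene_ids) {
  idx <- match(gene_ids, colnames(X))
  if (anyNA(idx)) {
    miss <- gene_ids[is.na(idx)]
    stop("dataset is missing ", length(miss), " model gene(s): ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) ", ..." else "")
  }
  X[, idx, drop = FALSE]
}

#' Top-weighted genes of a contrastive component
#'
#' Ranks genes on one component by absolute loading, reporting magnitude
#' and sign separately (the sign distinguishes genes elevated versus
#' depleted along the component). Equal magnitudes are ordered
#' lexicographically by gene symbol.
#'
#' @param model A \code{cocost_model}.
#' @param component Component index, 1-based.
#' @param top_k How many genes to return (default 20); values larger than
#'   the gene count return all genes.
#' @return \code{data.frame} with columns \code{gene}, \code{weight}
#'   (absolute loading), \code{sign} (\code{"+"} or \code{"-"}).
#' @export
top_genes <- function(model, component, top_k = 20) {
  stopifnot(inherits(model, "cocost_model"))
  if (component < 1 || component > ncol(model$W))
    stop("component must be in 1..", ncol(model$W))
  w <- model$W[, component]
  ord <- order(-abs(w), model$gene_ids)
  ord <- ord[seq_len(min(top_k, length(w)))]
  data.frame(gene = model$gene_ids[ord],
             weight = abs(w[ord]),
             sign = ifelse(w[ord] >= 0, "+", "-"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Background Rayleigh quotients of the fitted components
#'
#' Returns \code{w_i^T B w_i} for each component, where \code{B} is a
#' background scatter matrix. As the contrastive parameter grows, these
#' quotients are driven toward zero for positive-eigenvalue components —
#' a diagnostic that the projection has escaped the background's range
#' space.
#'
#' @param model A \code{cocost_model}.
#' @param background_scatter Symmetric positive semidefinite d x d matrix
#'   (e.g. from \code{\link{filtered_scatter}} on the background slice).
#' @return Numeric vector, one quotient per component.
#' @export
background_rayleigh <- function(model, background_scatter) {
  stopifnot(inherits(model, "cocost_model"))
  B <- as.matrix(background_scatter)
  if (nrow(B) != nrow(model$W))
    stop("scatter dimension does not match the model's gene count")
  colSums(model$W * (B %*% model$W))
}

#' Serialize a fitted model to a directory
#'
#' Writes a metadata JSON (hyperparameters, gene ids, eigenvalues) plus a
#' TSV of the loading matrix at 17 significant digits, so that
#' \code{\link{load_cocost}} restores the model to full float precision.
#'
#' @param model A \code{cocost_model}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
save_cocost <- function(model, dir) {
  stopifnot(inherits(model, "cocost_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(package = "cocost", model = "cocost_model",
               eta = model$eta, mu1 = model$mu1, mu2 = model$mu2,
               k = model$k, t_b = model$t_b, t_t = model$t_t,
               graph_mode = model$graph_mode,
               p_requested = model$p_requested,
               n_components = ncol(model$W),
               eigenvalues = model$eigenvalues,
               spectrum = model$spectrum,
               gene_ids = model$gene_ids)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  write_embedding(model$W, model$gene_ids, file.path(dir, "W.tsv"))
  invisible(dir)
}

#' Restore a model saved by \code{\link{save_cocost}}
#'
#' @param dir Directory written by \code{\link{save_cocost}}.
#' @return A \code{cocost_model}.
#' @export
load_cocost <- function(dir) {
  meta_path <- file.path(dir, "model.json")
  if (!file.exists(meta_path)) stop("not a model directory: ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  W <- read_embedding(file.path(dir, "W.tsv"))
  W <- W[meta$gene_ids, , drop = FALSE]
  ncomp <- if (!is.null(meta$n_components)) meta$n_components else ncol(W)
  colnames(W) <- if (ncomp) paste0("CC", seq_len(ncomp)) else NULL
  structure(list(W = W, eigenvalues = as.numeric(meta$eigenvalues),
                 spectrum = as.numeric(meta$spectrum),
                 gene_ids = meta$gene_ids, eta = meta$eta, mu1 = meta$mu1,
                 mu2 = meta$mu2, k = as.integer(meta$k), t_b = meta$t_b,
                 t_t = meta$t_t, graph_mode = meta$graph_mode,
                 p_requested = as.integer(meta$p_requested)),
            class = "cocost_model")
}
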