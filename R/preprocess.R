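#' Normalize raw counts
#'
#' Depth-normalizes and log-transforms a raw counts layer. Method
#' \code{"log_cpm"} scales each spot's counts to a common total
#' (\code{scale_factor}) and applies \code{log1p}; \code{"vst_like"} applies
#' the same per-spot depth scaling and log transform, and additionally marks
#' the dataset so that \code{\link{select_hvg}} ranks genes by a clipped
#' standardized variance around a fitted mean-variance trend rather than by
#' plain variance; \code{"none"} leaves values untouched (useful when the
#' input is already normalized upstream). All-zero spots cannot be depth
#' scaled and are dropped with a warning.
#'
#' @param ds A \code{spatial_dataset} with layer \code{"raw"}.
#' @param method One of \code{"log_cpm"}, \code{"vst_like"}, \code{"none"}.
#' @param scale_factor Per-spot total after depth scaling (default 1e4).
#' @return A \code{spatial_dataset} with layer \code{"normalized"}.
#' @export
normalize_counts <- function(ds, method = c("log_cpm", "vst_like", "none"),
                             scale_factor = 1e4) {
  stopifnot_dataset(ds)
  method <- match.arg(method)
  if (ds$layer != "raw")
    stop("normalize_counts expects a raw layer, got '", ds$layer, "'")
  X <- expr_matrix(ds)
  if (method == "none") {
    out <- spatial_dataset(X, ds$coords, ds$gene_ids, ds$spot_ids,
                           layer = "normalized")
    attr(out, "normalization") <- "none"
    return(out)
  }
  totals <- rowSums(X)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero spot(s) dropped during normalization")
    X <- X[!zero, , drop = FALSE]
    totals <- totals[!zero]
  }
  raw_kept <- X
  Xn <- log1p(X / totals * scale_factor)
  out <- spatial_dataset(Xn,
                         if (is.null(ds$coords)) NULL
                         else ds$coords[!zero, , drop = FALSE],
                         ds$gene_ids, ds$spot_ids[!zero],
                         layer = "normalized")
  attr(out, "normalization") <- method
  if (method == "vst_like") attr(out, "raw_counts") <- raw_kept
  out
}

#' Select highly variable genes
#'
#' Retains the \code{n} genes with the largest dispersion. The ranking
#' statistic is the per-gene variance of the normalized values; for
#' datasets normalized with \code{method = "vst_like"} it is the variance
#' of clipped standardized counts around a loess mean-variance trend (the
#' variance-stabilizing selection popularized by single-cell toolkits).
#' Ties at the cutoff are broken by lexicographic gene symbol so that the
#' selection is deterministic.
#'
#' @param ds A normalized \code{spatial_dataset}.
#' @param n Number of genes to keep.
#' @return A \code{spatial_dataset} restricted to the selected genes, in
#'   decreasing-dispersion order.
#' @export
select_hvg <- function(ds, n) {
  stopifnot_dataset(ds)
  if (ds$layer != "normalized")
    stop("select_hvg expects a normalized layer")
  d <- n_genes(ds)
  if (n > d) stop("n (", n, ") exceeds gene count (", d, ")")
  raw <- attr(ds, "raw_counts")
  score <- if (!is.null(raw)) .vst_standardized_variance(raw)
           else apply(expr_matrix(ds), 2, stats::var)
  ord <- order(-score, ds$gene_ids)
  keep <- ord[seq_len(n)]   # deterministic rank order, invariant to input order
  X <- expr_matrix(ds)[, keep, drop = FALSE]
  out <- spatial_dataset(X, ds$coords, ds$gene_ids[keep], ds$spot_ids,
                         layer = "normalized")
  attr(out, "normalization") <- attr(ds, "normalization")
  out
}

# Clipped standardized variance per gene on raw counts: fit a loess trend of
# log10(var) ~ log10(mean), standardize counts with the trend sd, clip at
# sqrt(n_spots), and return the variance of the clipped values.
.vst_standardized_variance <- function(raw) {
  mu <- colMeans(raw)
  v <- apply(raw, 2, stats::var)
  score <- numeric(length(mu))
  ok <- mu > 0 & v > 0
  if (sum(ok) >= 5) {
    fit <- stats::loess(log10(v[ok]) ~ log10(mu[ok]), span = 0.5,
                        degree = 2)
    sd_exp <- sqrt(10^stats::predict(fit))
    n <- nrow(raw)
    z <- sweep(sweep(raw[, ok, drop = FALSE], 2, mu[ok], "-"),
               2, sd_exp, "/")
    z <- pmin(z, sqrt(n))
    score[ok] <- apply(z, 2, stats::var)
  } else {
    score[ok] <- v[ok]
  }
  score
}

#' Standardize genes to zero mean and unit variance
#'
#' Centers and scales each gene (column) across spots. Genes with zero
#' variance are set to all-zero and recorded in the
#' \code{"zero_variance_genes"} attribute. The operation is idempotent.
#'
#' @param ds A normalized (or already standardized) \code{spatial_dataset}.
#' @return A \code{spatial_dataset} with layer \code{"standardized"}.
#' @export
standardize_genes <- function(ds) {
  stopifnot_dataset(ds)
  if (ds$layer == "raw")
    stop("standardize_genes expects a normalized layer; normalize first")
  X <- expr_matrix(ds)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  flat <- sd < .Machine$double.eps
  sd[flat] <- 1
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sd, "/")
  Z[, flat] <- 0
  out <- spatial_dataset(Z, ds$coords, ds$gene_ids, ds$spot_ids,
                         layer = "standardized")
  attr(out, "zero_variance_genes") <- ds$gene_ids[flat]
  out
}

#' Align two datasets to a shared gene namespace
#'
#' Restricts both slices to the intersection of their gene sets, in the
#' background's gene order, so that a projection learned on the pair can be
#' applied to either slice. The intersection size is reported via
#' \code{message}; an empty intersection is an error.
#'
#' @param background,target \code{spatial_dataset} objects.
#' @return A list with elements \code{background} and \code{target}, both
#'   carrying identical \code{gene_ids}.
#' @export
align_genes <- function(background, target) {
  stopifnot_dataset(background, "background")
  stopifnot_dataset(target, "target")
  shared <- intersect(background$gene_ids, target$gene_ids)
  if (length(shared) == 0) stop("no shared genes between the two datasets")
  message("gene intersection: ", length(shared), " genes")
  list(background = .subset_genes(background, shared),
       target = .subset_genes(target, shared))
}

.subset_genes <- function(ds, genes) {
  idx <- match(genes, ds$gene_ids)
  out <- spatial_dataset(ds$expr[, idx, drop = FALSE], ds$coords,
                         genes, ds$spot_ids, layer = ds$layer)
  attr(out, "normalization") <- attr(ds, "normalization")
  raw <- attr(ds, "raw_counts")
  if (!is.null(raw)) attr(out, "raw_counts") <- raw[, idx, drop = FALSE]
  out
}
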