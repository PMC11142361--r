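#' Construct a spatial transcriptomics dataset
#'
#' Bundles a spots-by-genes expression matrix with per-spot 2D coordinates
#' and identifier vectors into a single validated object, the unit of data
#' every other function in the package consumes.
#'
#' @param expr Numeric matrix (or \code{Matrix} sparse matrix), spots in
#'   rows and genes in columns.
#' @param coords Numeric matrix or data frame with one row per spot and two
#'   columns (x, y); array coordinates or microns. May be \code{NULL} for
#'   purely molecular analyses, in which case spatial graph construction is
#'   unavailable.
#' @param gene_ids Character vector of unique gene symbols, one per column
#'   of \code{expr}.
#' @param spot_ids Character vector of unique spot barcodes, one per row of
#'   \code{expr}.
#' @param layer One of \code{"raw"}, \code{"normalized"},
#'   \code{"standardized"}; records how far along the preprocessing chain
#'   the values are. Raw layers must be nonnegative and finite.
#'
#' @return An object of class \code{spatial_dataset}: a list with elements
#'   \code{expr}, \code{coords}, \code{gene_ids}, \code{spot_ids},
#'   \code{layer}.
#' @export
spatial_dataset <- function(expr, coords = NULL, gene_ids = NULL,
                            spot_ids = NULL, layer = c("raw", "normalized",
                                                       "standardized")) {
  layer <- match.arg(layer)
  if (is.data.frame(expr)) expr <- as.matrix(expr)
  if (is.null(gene_ids)) gene_ids <- colnames(expr)
  if (is.null(spot_ids)) spot_ids <- rownames(expr)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(expr)))
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(expr)))
  gene_ids <- as.character(gene_ids)
  spot_ids <- as.character(spot_ids)

  if (nrow(expr) != length(spot_ids))
    stop("nrow(expr) must equal length(spot_ids)")
  if (ncol(expr) != length(gene_ids))
    stop("ncol(expr) must equal length(gene_ids)")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(spot_ids)) stop("spot_ids must be unique")
  if (!is.null(coords)) {
    if (is.data.frame(coords)) coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
    if (nrow(coords) != nrow(expr))
      stop("coords must have one row per spot")
    if (ncol(coords) != 2) stop("coords must have exactly two columns (x, y)")
    if (!all(is.finite(coords))) stop("coords must be finite")
    rownames(coords) <- spot_ids
    colnames(coords) <- c("x", "y")
  }
  vals <- if (inherits(expr, "Matrix")) expr@x else expr
  if (layer == "raw") {
    if (length(vals) && (any(!is.finite(vals)) || any(vals < 0)))
      stop("raw layer requires finite, nonnegative expression values")
  } else {
    if (length(vals) && any(!is.finite(vals)))
      stop(layer, " layer must not contain NaN/Inf")
  }
  dimnames(expr) <- list(spot_ids, gene_ids)

  structure(list(expr = expr, coords = coords, gene_ids = gene_ids,
                 spot_ids = spot_ids, layer = layer),
            class = "spatial_dataset")
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("spatial_dataset: %d spots x %d genes [layer: %s]%s\n",
              length(x$spot_ids), length(x$gene_ids), x$layer,
              if (is.null(x$coords)) " (no coordinates)" else ""))
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$expr)

#' Number of spots in a dataset
#' @param ds A \code{spatial_dataset}.
#' @return Integer spot count.
#' @export
n_spots <- function(ds) length(ds$spot_ids)

#' Number of genes in a dataset
#' @param ds A \code{spatial_dataset}.
#' @return Integer gene count.
#' @export
n_genes <- function(ds) length(ds$gene_ids)

# Dense numeric expression matrix (spots x genes), always base `matrix`.
expr_matrix <- function(ds) {
  m <- as.matrix(ds$expr)
  storage.mode(m) <- "double"
  m
}

stopifnot_dataset <- function(ds, arg = "ds") {
  if (!inherits(ds, "spatial_dataset"))
    stop(sprintf("'%s' must be a spatial_dataset", arg))
  invisible(ds)
}
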