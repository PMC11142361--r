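#' Read a spatial transcriptomics slice from disk
#'
#' Assembles a \code{\link{spatial_dataset}} from an expression matrix and a
#' spot coordinate table. Two matrix layouts are supported: the 10x-style
#' MatrixMarket triplet (an \code{.mtx} file with companion gene and barcode
#' text files alongside) and plain delimited text with a header row.
#'
#' Spots present in the matrix but missing from the coordinate table are
#' dropped (the count is reported via \code{message}); the join is by
#' barcode string, preserving matrix file order, so differently sorted
#' inputs are handled. Zero overlap between matrix barcodes and coordinate
#' barcodes is an error.
#'
#' @param matrix_path Path to the matrix file (\code{.mtx} for
#'   \code{format = "mtx_triplet"}; TSV/CSV otherwise).
#' @param coords_path Path to a delimited coordinate table. Recognized
#'   barcode columns: \code{spot_id}, \code{barcode}; coordinates come from
#'   \code{x}/\code{y}, \code{array_col}/\code{array_row}, or
#'   \code{pxl_col_in_fullres}/\code{pxl_row_in_fullres} (Visium
#'   tissue-positions style). Override with \code{coord_cols}.
#' @param format \code{"mtx_triplet"} or \code{"delimited"}.
#' @param orientation Matrix orientation on disk: \code{"genes_by_spots"}
#'   (10x convention; default for MTX) or \code{"spots_by_genes"} (default
#'   for delimited text).
#' @param coord_cols Optional named character vector mapping
#'   \code{c(id=, x=, y=)} to column names of the coordinate table.
#'
#' @return A \code{spatial_dataset} with layer \code{"raw"}, spots ordered
#'   as in the matrix file (restricted to spots with coordinates).
#' @export
read_dataset <- function(matrix_path, coords_path,
                         format = c("mtx_triplet", "delimited"),
                         orientation = NULL, coord_cols = NULL) {
  format <- match.arg(format)
  if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
  if (!file.exists(coords_path)) stop("coords file not found: ", coords_path)
  if (is.null(orientation))
    orientation <- if (format == "mtx_triplet") "genes_by_spots"
                   else "spots_by_genes"
  orientation <- match.arg(orientation, c("genes_by_spots", "spots_by_genes"))

  if (format == "mtx_triplet") {
    mat <- tryCatch(Matrix::readMM(matrix_path),
                    error = function(e) stop("malformed MatrixMarket file '",
                                             matrix_path, "': ",
                                             conditionMessage(e)))
    dir <- dirname(matrix_path)
    genes_file <- .find_companion(dir, c("features.tsv", "genes.tsv",
                                         "features.txt", "genes.txt"))
    bc_file <- .find_companion(dir, c("barcodes.tsv", "barcodes.txt"))
    gene_tab <- utils::read.table(genes_file, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE, quote = "")
    # 10x features files carry (id, symbol, type); use the symbol column
    gene_ids <- if (ncol(gene_tab) >= 2) gene_tab[[2]] else gene_tab[[1]]
    gene_ids <- make.unique(as.character(gene_ids))
    spot_ids <- as.character(utils::read.table(bc_file, sep = "\t",
                                               header = FALSE,
                                               stringsAsFactors = FALSE)[[1]])
    if (orientation == "genes_by_spots") mat <- Matrix::t(mat)
    if (nrow(mat) != length(spot_ids) || ncol(mat) != length(gene_ids))
      stop("matrix dimensions do not match companion gene/barcode files")
    expr <- mat
  } else {
    tab <- utils::read.table(matrix_path, sep = .sniff_sep(matrix_path),
                             header = TRUE, row.names = 1, check.names = FALSE,
                             stringsAsFactors = FALSE, quote = "")
    expr <- as.matrix(tab)
    if (!is.numeric(expr)) stop("malformed matrix: non-numeric entries in '",
                                matrix_path, "'")
    if (orientation == "genes_by_spots") expr <- t(expr)
    spot_ids <- rownames(expr)
    gene_ids <- colnames(expr)
  }

  coords <- read_coords(coords_path, coord_cols)
  keep <- spot_ids %in% rownames(coords)
  n_drop <- sum(!keep)
  if (sum(keep) == 0)
    stop("no overlapping spot barcodes between matrix and coordinate table")
  if (n_drop > 0)
    message(n_drop, " spot(s) in matrix had no coordinates and were dropped")
  expr <- expr[keep, , drop = FALSE]
  spot_ids <- spot_ids[keep]
  coords <- coords[spot_ids, , drop = FALSE]

  spatial_dataset(expr, coords = coords, gene_ids = gene_ids,
                  spot_ids = spot_ids, layer = "raw")
}

.find_companion <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop("no companion file found in ", dir, " (tried: ",
       paste(candidates, collapse = ", "), ")")
}

.sniff_sep <- function(path) {
  line <- readLines(path, n = 1)
  if (grepl("\t", line)) "\t" else ","
}

#' Read a spot coordinate table
#'
#' @inheritParams read_dataset
#' @return Numeric matrix with columns \code{x}, \code{y}, rownames the
#'   spot barcodes.
#' @export
read_coords <- function(coords_path, coord_cols = NULL) {
  tab <- utils::read.table(coords_path, sep = .sniff_sep(coords_path),
                           header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, quote = "")
  if (is.null(coord_cols)) {
    id_col <- intersect(c("spot_id", "barcode"), names(tab))[1]
    xy <- if (all(c("x", "y") %in% names(tab))) c("x", "y")
          else if (all(c("array_col", "array_row") %in% names(tab)))
            c("array_col", "array_row")
          else if (all(c("pxl_col_in_fullres", "pxl_row_in_fullres") %in%
                       names(tab)))
            c("pxl_col_in_fullres", "pxl_row_in_fullres")
          else NA
    if (is.na(id_col) || anyNA(xy))
      stop("could not identify barcode/x/y columns in coordinate table; ",
           "pass coord_cols = c(id=, x=, y=)")
    coord_cols <- c(id = id_col, x = xy[1], y = xy[2])
  }
  missing_cols <- setdiff(coord_cols, names(tab))
  if (length(missing_cols))
    stop("coordinate table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  m <- as.matrix(tab[, c(coord_cols[["x"]], coord_cols[["y"]])])
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y")
  rownames(m) <- as.character(tab[[coord_cols[["id"]]]])
  if (anyDuplicated(rownames(m))) stop("duplicate barcodes in coordinate table")
  m
}

#' Write an embedding to a delimited file
#'
#' Writes a spots-by-components matrix as a TSV with header
#' \code{spot_id, CC1..CCp}. Values are written with 17 significant digits
#' so that \code{\link{read_embedding}} reproduces the matrix bit-for-bit.
#'
#' @param Z Numeric matrix, spots in rows.
#' @param spot_ids Character vector, one id per row of \code{Z}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_embedding <- function(Z, spot_ids, path) {
  Z <- as.matrix(Z)
  if (ncol(Z) == 0) stop("embedding has no components (p = 0)")
  if (nrow(Z) != length(spot_ids))
    stop("nrow(Z) must equal length(spot_ids)")
  header <- paste(c("spot_id", paste0("CC", seq_len(ncol(Z)))),
                  collapse = "\t")
  body <- vapply(seq_len(nrow(Z)), function(i)
    paste(c(spot_ids[i], sprintf("%.17g", Z[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an embedding written by \code{\link{write_embedding}}
#'
#' @param path File path.
#' @return Numeric matrix with rownames the spot ids and columns
#'   \code{CC1..CCp}.
#' @export
read_embedding <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  m
}

#' Export an affinity graph as an edge list
#'
#' @param graph An \code{\link{affinity_graph}}.
#' @param path Output TSV path; columns \code{i}, \code{j}, \code{weight}
#'   with \code{i < j} (the graph is symmetric).
#' @return Invisibly, \code{path}.
#' @export
write_edge_list <- function(graph, path) {
  S <- graph$S
  idx <- which(upper.tri(S) & S > 0, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], weight = S[idx])
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
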