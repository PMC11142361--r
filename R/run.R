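#' Default run configuration
#'
#' Returns the fully resolved default configuration as a nested list;
#' user-supplied YAML/JSON configs are merged over these defaults, so the
#' echo written next to every run lists every parameter that affected the
#' output.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    input = list(background_matrix = NULL, background_coords = NULL,
                 target_matrix = NULL, target_coords = NULL,
                 format = "delimited", orientation = NULL),
    preprocess = list(normalization = "log_cpm", n_hvg = NULL,
                      standardize = TRUE),
    graph = list(mode = "molecular", k = NULL, t = "auto",
                 mu1 = 0.5, mu2 = 0.5),
    model = list(eta = 1, p = 30, kernel = NULL, rho = NULL),
    cluster = list(method = "kmeans", n_clusters = 6, resolution = 1),
    seed = 1
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load a run configuration file
#'
#' Reads a YAML (or JSON) configuration and merges it over
#' \code{\link{default_config}}.
#'
#' @param path Config file path.
#' @return Fully resolved configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  .merge_config(default_config(), cfg)
}

.prepare_pair <- function(background, target, cfg) {
  pp <- cfg$preprocess
  bg <- normalize_counts(background, pp$normalization)
  tg <- normalize_counts(target, pp$normalization)
  if (!is.null(pp$n_hvg)) {
    # variable genes are chosen on the target slice, where the structure
    # of interest lives, and the same panel is applied to both slices
    tg <- select_hvg(tg, pp$n_hvg)
    keep <- intersect(tg$gene_ids, bg$gene_ids)
    bg <- .subset_genes(bg, keep)
    tg <- .subset_genes(tg, keep)
  }
  al <- align_genes(bg, tg)
  if (isTRUE(pp$standardize)) {
    al$background <- standardize_genes(al$background)
    al$target <- standardize_genes(al$target)
  }
  al
}

#' Fit a model from a run configuration
#'
#' End-to-end driver behind the \code{fit} CLI subcommand: reads the two
#' slices, preprocesses them, fits the (linear or kernel) contrastive
#' model, and writes into \code{out_dir}: the serialized model
#' (\code{model/}), the target embedding (\code{Zt.tsv}), the background
#' embedding (\code{Zb.tsv}), and a fully resolved parameter echo
#' (\code{config_resolved.yaml}). Identical configuration and seed yield
#' byte-identical outputs. On error, partial outputs are removed.
#'
#' @param config Path to a YAML/JSON config, or a configuration list. A
#'   preassembled pair may instead be passed via \code{background} /
#'   \code{target}.
#' @param out_dir Output directory.
#' @param background,target Optional raw-layer \code{spatial_dataset}
#'   objects, overriding the config's input paths.
#' @return Invisibly, the fitted model.
#' @export
run_fit <- function(config, out_dir, background = NULL, target = NULL) {
  cfg <- if (is.character(config)) load_config(config)
         else .merge_config(default_config(), config)
  created <- !dir.exists(out_dir)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(out_dir, recursive = TRUE))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  set.seed(cfg$seed)
  if (is.null(background)) {
    inp <- cfg$input
    background <- read_dataset(inp$background_matrix, inp$background_coords,
                               format = inp$format,
                               orientation = inp$orientation)
    target <- read_dataset(inp$target_matrix, inp$target_coords,
                           format = inp$format,
                           orientation = inp$orientation)
  }
  pair <- .prepare_pair(background, target, cfg)

  g <- cfg$graph; m <- cfg$model
  if (is.null(m$kernel)) {
    model <- cocost(pair$background, pair$target, eta = m$eta,
                    mu1 = g$mu1, mu2 = g$mu2, k = g$k, t = g$t, p = m$p,
                    graph_mode = g$mode)
    save_cocost(model, file.path(out_dir, "model"))
    Zt <- cocost_transform(model, pair$target)
    Zb <- cocost_transform(model, pair$background)
    cfg$graph$k <- model$k
    cfg$graph$t_b <- model$t_b
    cfg$graph$t_t <- model$t_t
  } else {
    ks <- do.call(kernel_spec, m$kernel)
    model <- cocost_kernel(pair$background, pair$target, kernel = ks,
                           eta = m$eta, mu1 = g$mu1, mu2 = g$mu2,
                           k = g$k, t = g$t, p = m$p, graph_mode = g$mode,
                           rho = m$rho)
    Zt <- cocost_kernel_transform(model, pair$target)
    Zb <- cocost_kernel_transform(model, pair$background)
    cfg$model$rho <- model$rho
    cfg$graph$k <- model$k
  }
  if (ncol(Zt) == 0) stop("no positive-eigenvalue components were found")
  write_embedding(Zt, pair$target$spot_ids, file.path(out_dir, "Zt.tsv"))
  write_embedding(Zb, pair$background$spot_ids, file.path(out_dir, "Zb.tsv"))
  yaml::write_yaml(cfg, file.path(out_dir, "config_resolved.yaml"))
  ok <- TRUE
  invisible(model)
}

#' Transform a new slice with a saved model
#'
#' Driver behind the \code{transform} CLI subcommand: loads a model
#' directory written by \code{\link{run_fit}}/\code{\link{save_cocost}},
#' preprocesses the new slice the same way (normalize, restrict to the
#' model genes, standardize with the slice's own statistics), and writes
#' its embedding.
#'
#' @param model_dir Model directory.
#' @param matrix_path,coords_path Input files for the new slice.
#' @param out_path Output embedding TSV.
#' @param format,orientation Passed to \code{\link{read_dataset}}.
#' @param normalization Normalization applied before projection (should
#'   match the fit; default \code{"log_cpm"}).
#' @return Invisibly, the embedding matrix.
#' @export
run_transform <- function(model_dir, matrix_path, coords_path, out_path,
                          format = "delimited", orientation = NULL,
                          normalization = "log_cpm") {
  model <- load_cocost(model_dir)
  ds <- read_dataset(matrix_path, coords_path, format = format,
                     orientation = orientation)
  ds <- normalize_counts(ds, normalization)
  missing <- setdiff(model$gene_ids, ds$gene_ids)
  if (length(missing))
    stop("slice is missing ", length(missing), " model gene(s): ",
         paste(utils::head(missing, 10), collapse = ", "))
  ds <- .subset_genes(ds, model$gene_ids)
  ds <- standardize_genes(ds)
  Z <- cocost_transform(model, ds)
  write_embedding(Z, ds$spot_ids, out_path)
  invisible(Z)
}

#' Write a synthetic pair in the delimited format the readers accept
#'
#' Driver behind the \code{synth} CLI subcommand. Writes, per slice, a
#' spots-by-genes count matrix TSV and a coordinate TSV, plus the true
#' domain labels.
#'
#' @param config A \code{\link{synthetic_config}} (or a list of its
#'   arguments, e.g. parsed from YAML).
#' @param out_dir Output directory.
#' @return Invisibly, the generated pair (see \code{\link{generate_pair}}).
#' @export
run_synth <- function(config, out_dir) {
  if (!inherits(config, "synthetic_config")) {
    if (!is.null(config$shared_domains))
      config$shared_domains <- lapply(config$shared_domains,
                                      function(a) do.call(synthetic_domain, a))
    if (!is.null(config$target_only_domains))
      config$target_only_domains <-
        lapply(config$target_only_domains,
               function(a) do.call(synthetic_domain, a))
    config <- do.call(synthetic_config, config)
  }
  pair <- generate_pair(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (side in c("background", "target")) {
    ds <- pair[[side]]
    mat <- as.data.frame(as.matrix(ds$expr))
    utils::write.table(cbind(spot_id = ds$spot_ids, mat),
                       file.path(out_dir, paste0(side, "_matrix.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(spot_id = ds$spot_ids,
                                  x = ds$coords[, 1], y = ds$coords[, 2]),
                       file.path(out_dir, paste0(side, "_coords.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(data.frame(spot_id = pair$target$spot_ids,
                                label = pair$labels_t),
                     file.path(out_dir, "target_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pair)
}
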