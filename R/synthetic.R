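#' Describe a planted spatial domain
#'
#' A rectangular region of the spot lattice carrying a gene expression
#' program. The program has a mean component (\code{effect_size} added to
#' the log-intensity of every program gene inside the region) and a
#' stochastic component: \code{n_factors} latent activity factors, drawn
#' per spot with variance \code{variance_scale}, mixed onto the program
#' genes through fixed random loadings. A large \code{variance_scale}
#' with several factors emulates heterogeneous dominant tissue (the
#' structure a contrastive analysis should suppress); a small one with a
#' single factor emulates a subtle localized lesion.
#'
#' @param rows,cols Integer ranges \code{c(from, to)} of lattice rows and
#'   columns covered by the region.
#' @param genes Integer indices of the program genes.
#' @param effect_size Mean log-intensity shift on program genes inside
#'   the region.
#' @param variance_scale Variance of each latent activity factor across
#'   the region's spots.
#' @param n_factors Number of latent factors (default 1).
#' @return An object of class \code{synthetic_domain}.
#' @export
synthetic_domain <- function(rows, cols, genes, effect_size = 1,
                             variance_scale = 1, n_factors = 1) {
  stopifnot(length(rows) == 2, length(cols) == 2, rows[1] <= rows[2],
            cols[1] <= cols[2], length(genes) >= 1, variance_scale >= 0,
            n_factors >= 1)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 genes = as.integer(genes), effect_size = effect_size,
                 variance_scale = variance_scale,
                 n_factors = as.integer(n_factors)),
            class = "synthetic_domain")
}

#' Configuration for the paired-slice simulator
#'
#' Defines the study scenario the simulator emulates: a spot lattice, a
#' gene panel, a set of spatial domains shared by both slices (dominant,
#' high-variance structure such as normal parenchyma), and additional
#' domains present only in the target slice (low-variance lesions such as
#' hyperplasia foci). The configuration enforces the premise that makes
#' contrastive analysis necessary: every target-only domain must have
#' strictly smaller \code{variance_scale} than the strongest shared
#' domain, so the interesting structure is masked by the dominant one.
#'
#' The default scenario plants one dominant shared band (200 spots,
#' 60 program genes, 10 latent factors of variance 2 — heterogeneous
#' normal tissue) and one 25-spot target-only hotspot (20 program genes,
#' one factor of variance 0.2, one tenth of the dominant variance).
#'
#' @param grid \code{c(rows, cols)} of the square spot lattice.
#' @param n_genes Gene panel size.
#' @param shared_domains List of \code{\link{synthetic_domain}} present in
#'   both slices.
#' @param target_only_domains List of \code{\link{synthetic_domain}}
#'   present only in the target slice.
#' @param noise_sd Per-gene Gaussian noise SD on the log-intensity scale.
#' @param baseline_log_mean,baseline_log_sd Per-gene baseline
#'   log-intensities are drawn N(baseline_log_mean, baseline_log_sd^2).
#' @param seed Integer seed; the generated pair is a deterministic
#'   function of the full configuration.
#' @return An object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(grid = c(20, 20), n_genes = 150,
                             shared_domains = list(
                               synthetic_domain(rows = c(1, 10),
                                                cols = c(1, 20),
                                                genes = 1:60,
                                                effect_size = 0.3,
                                                variance_scale = 2,
                                                n_factors = 10)),
                             target_only_domains = list(
                               synthetic_domain(rows = c(13, 17),
                                                cols = c(13, 17),
                                                genes = 61:80,
                                                effect_size = 1,
                                                variance_scale = 0.2,
                                                n_factors = 1)),
                             noise_sd = 0.2,
                             baseline_log_mean = log(5),
                             baseline_log_sd = 0.2,
                             seed = 1) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 2, all(grid >= 1), n_genes >= 1, noise_sd >= 0)
  all_domains <- c(shared_domains, target_only_domains)
  for (dm in all_domains) {
    if (!inherits(dm, "synthetic_domain"))
      stop("domains must be synthetic_domain objects")
    if (dm$rows[2] > grid[1] || dm$cols[2] > grid[2] ||
        dm$rows[1] < 1 || dm$cols[1] < 1)
      stop("domain region lies outside the ", grid[1], "x", grid[2],
           " grid")
    if (max(dm$genes) > n_genes)
      stop("domain program genes exceed n_genes")
  }
  # regions must not overlap: each spot carries exactly one domain label
  occ <- matrix(0L, grid[1], grid[2])
  for (dm in all_domains) {
    occ[dm$rows[1]:dm$rows[2], dm$cols[1]:dm$cols[2]] <-
      occ[dm$rows[1]:dm$rows[2], dm$cols[1]:dm$cols[2]] + 1L
    if (any(occ > 1)) stop("domain regions overlap")
  }
  if (length(target_only_domains)) {
    if (!length(shared_domains))
      stop("target-only domains require at least one shared domain")
    vmax <- max(vapply(shared_domains, `[[`, numeric(1), "variance_scale"))
    vtar <- vapply(target_only_domains, `[[`, numeric(1), "variance_scale")
    if (any(vtar >= vmax))
      stop("target-only domains must have strictly smaller variance_scale ",
           "than the dominant shared domain")
  }
  structure(list(grid = grid, n_genes = as.integer(n_genes),
                 shared_domains = shared_domains,
                 target_only_domains = target_only_domains,
                 noise_sd = noise_sd,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a background/target slice pair with planted domains
#'
#' Simulates two spatially resolved slices over the configured lattice.
#' Gene counts are log-normal-Poisson: a per-gene baseline log-intensity,
#' plus domain program effects for spots inside domain regions, plus
#' Gaussian noise, exponentiated and Poisson-sampled to nonnegative
#' integer counts. Domain loadings are drawn once per configuration, so
#' shared domains express the same program in both slices; spot-level
#' activities and noise are independent between slices. The output is a
#' deterministic function of the configuration (including its seed).
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return List with \code{background} and \code{target} (raw-layer
#'   \code{spatial_dataset}s on the lattice coordinates), and
#'   \code{labels_b}, \code{labels_t}: integer domain labels per spot
#'   (0 = no domain; shared domains numbered first, then target-only
#'   domains, in configuration order). The pre-Poisson log-intensity
#'   matrices are attached as attributes \code{latent_b}, \code{latent_t}.
#' @export
generate_pair <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nr <- config$grid[1]; nc <- config$grid[2]
  n <- nr * nc; g <- config$n_genes
  coords <- cbind(x = rep(seq_len(nc), each = nr),
                  y = rep(seq_len(nr), times = nc))
  baseline <- stats::rnorm(g, config$baseline_log_mean,
                           config$baseline_log_sd)

  all_domains <- c(config$shared_domains, config$target_only_domains)
  n_shared <- length(config$shared_domains)
  # fixed loadings per domain/factor, shared across slices; unit-norm
  # columns so variance_scale is the variance of the structure itself
  loadings <- lapply(all_domains, function(dm) {
    L <- matrix(stats::rnorm(length(dm$genes) * dm$n_factors),
                length(dm$genes), dm$n_factors)
    sweep(L, 2, sqrt(colSums(L^2)), "/")
  })

  spot_in <- function(dm)
    which(coords[, "y"] >= dm$rows[1] & coords[, "y"] <= dm$rows[2] &
          coords[, "x"] >= dm$cols[1] & coords[, "x"] <= dm$cols[2])

  labels <- integer(n)
  for (i in seq_along(all_domains))
    labels[spot_in(all_domains[[i]])] <- i
  labels_b <- ifelse(labels > n_shared, 0L, labels)
  labels_t <- labels

  make_slice <- function(domain_idx, prefix) {
    latent <- matrix(baseline, n, g, byrow = TRUE)
    for (i in domain_idx) {
      dm <- all_domains[[i]]
      spots <- spot_in(dm)
      latent[spots, dm$genes] <- latent[spots, dm$genes] + dm$effect_size
      act <- matrix(stats::rnorm(length(spots) * dm$n_factors, 0,
                                 sqrt(dm$variance_scale)),
                    length(spots), dm$n_factors)
      latent[spots, dm$genes] <- latent[spots, dm$genes] +
        act %*% t(loadings[[i]])
    }
    latent <- latent + matrix(stats::rnorm(n * g, 0, config$noise_sd), n, g)
    counts <- matrix(stats::rpois(n * g, exp(latent)), n, g)
    ds <- spatial_dataset(counts, coords = coords,
                          gene_ids = sprintf("gene%03d", seq_len(g)),
                          spot_ids = sprintf("%s_spot%04d", prefix,
                                             seq_len(n)),
                          layer = "raw")
    list(ds = ds, latent = latent)
  }

  bg <- make_slice(seq_len(n_shared), "bg")
  tg <- make_slice(seq_along(all_domains), "tg")

  out <- list(background = bg$ds, target = tg$ds,
              labels_b = labels_b, labels_t = labels_t)
  attr(out, "latent_b") <- bg$latent
  attr(out, "latent_t") <- tg$latent
  out
}

#' Score how well an embedding recovers known domain labels
#'
#' Clusters the embedding with k-means (fixed seed, 10 restarts) and
#' scores the result against the true labels with the adjusted Rand index
#' and normalized mutual information. Both scores are invariant to label
#' permutations; 1 means perfect recovery, values near 0 chance level.
#'
#' @param embedding Numeric matrix, spots x p.
#' @param true_labels Vector of ground-truth labels, one per row.
#' @param n_clusters Number of k-means clusters.
#' @param seed Integer seed for the k-means restarts.
#' @return List with elements \code{ari} and \code{nmi}.
#' @export
evaluate_recovery <- function(embedding, true_labels, n_clusters,
                              seed = 1) {
  embedding <- as.matrix(embedding)
  if (nrow(embedding) != length(true_labels))
    stop("embedding rows must match label length")
  if (n_clusters > nrow(embedding))
    stop("n_clusters exceeds the number of spots")
  set.seed(seed)
  km <- stats::kmeans(embedding, centers = n_clusters, nstart = 10,
                      iter.max = 100)
  truth <- as.integer(factor(true_labels))
  list(ari = mclust::adjustedRandIndex(km$cluster, truth),
       nmi = igraph::compare(km$cluster, truth, method = "nmi"))
}

#' Benchmark hotspot recovery against a PCA baseline
#'
#' Runs the full pipeline on freshly simulated pairs over several seeds:
#' generate a pair, normalize, standardize, fit the contrastive model,
#' project the target onto the top \code{p} eigenvalue-scaled components,
#' and score k-means recovery (k = 2) of the target-only hotspot against
#' the hotspot-vs-rest truth. The baseline applies the identical protocol
#' to a plain PCA of the target slice alone (the \code{eta = 0},
#' \code{mu = 0} special case), which sees the same data but cannot
#' subtract the dominant shared structure.
#'
#' @param n_seeds Number of independent replicates.
#' @param base_seed Replicate r uses configuration seed
#'   \code{base_seed + r}.
#' @param config_fn Function(seed) returning a
#'   \code{\link{synthetic_config}}; defaults to the package's default
#'   scenario at that seed.
#' @param eta,mu,p Model hyperparameters (defaults 1, 0.5, 5).
#' @return \code{data.frame} with one row per seed: \code{seed},
#'   \code{ari_cocost}, \code{ari_pca}.
#' @export
benchmark_recovery <- function(n_seeds = 10, base_seed = 100,
                               config_fn = function(seed)
                                 synthetic_config(seed = seed),
                               eta = 1, mu = 0.5, p = 5) {
  out <- lapply(seq_len(n_seeds), function(r) {
    cfg <- config_fn(base_seed + r)
    pair <- generate_pair(cfg)
    bg <- standardize_genes(normalize_counts(pair$background, "log_cpm"))
    tg <- standardize_genes(normalize_counts(pair$target, "log_cpm"))
    hot_label <- length(cfg$shared_domains) + 1L
    hot <- as.integer(pair$labels_t == hot_label)
    fit <- cocost(bg, tg, eta = eta, mu1 = mu, mu2 = mu, p = p)
    Zc <- cocost_transform(fit, tg, scale = "eigenvalue")
    ari_c <- evaluate_recovery(Zc, hot, 2, seed = r)$ari
    pca <- cocost(tg, tg, eta = 0, mu1 = 0, mu2 = 0, p = p)
    Zp <- cocost_transform(pca, tg, scale = "eigenvalue")
    ari_p <- evaluate_recovery(Zp, hot, 2, seed = r)$ari
    data.frame(seed = base_seed + r, ari_cocost = ari_c, ari_pca = ari_p)
  })
  do.call(rbind, out)
}
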