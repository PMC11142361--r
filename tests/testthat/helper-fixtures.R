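# Shared fixtures, built in code at test time.

# Small standardized spots-by-genes matrix wrapped as a dataset.
std_dataset <- function(n, d, seed = 1, coords = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  spatial_dataset(X, coords = coords, layer = "standardized")
}

# Matrix with exactly orthonormal columns (n x p, p <= n).
orthonormal_cols <- function(n, p, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(n * p), n, p)))[, seq_len(p), drop = FALSE]
}

# Random symmetric PSD filter H = I - mu * Lbar from a random kNN graph.
random_filter <- function(n, seed = 1, mu = 0.5, k = 3) {
  set.seed(seed)
  pts <- matrix(rnorm(n * 2), n, 2)
  g <- suppressMessages(build_knn_affinity(pts, k = k, t = 1))
  laplacian_filter(normalized_laplacian(g), mu)
}

# Write a tiny delimited matrix + coords pair; returns the two paths.
write_delim_pair <- function(dir, expr, coords_ids = rownames(expr)) {
  mat_path <- file.path(dir, "matrix.tsv")
  coord_path <- file.path(dir, "coords.tsv")
  df <- data.frame(spot_id = rownames(expr), expr, check.names = FALSE)
  write.table(df, mat_path, sep = "\t", quote = FALSE, row.names = FALSE)
  set.seed(42)
  cd <- data.frame(spot_id = coords_ids,
                   x = seq_along(coords_ids),
                   y = rev(seq_along(coords_ids)))
  write.table(cd, coord_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mat_path, coords = coord_path)
}

# Small raw-count dataset on a lattice.
raw_lattice_dataset <- function(nr = 4, nc = 4, d = 6, seed = 7) {
  set.seed(seed)
  n <- nr * nc
  counts <- matrix(rpois(n * d, 8), n, d)
  coords <- cbind(x = rep(seq_len(nc), each = nr),
                  y = rep(seq_len(nr), times = nc))
  spatial_dataset(counts, coords = coords, layer = "raw")
}

expect_symmetric <- function(M, tol = 0) {
  expect_lte(max(abs(M - t(M))), tol)
}

# All-pairs reference construction of the kNN heat-kernel affinity,
# independent of the package's code path.
brute_force_affinity <- function(points, k, t) {
  n <- nrow(points)
  D2 <- as.matrix(dist(points))^2
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    others_i <- seq_len(n)[-i]
    knn_i <- others_i[order(D2[i, -i])[seq_len(k)]]
    others_j <- seq_len(n)[-j]
    knn_j <- others_j[order(D2[j, -j])[seq_len(k)]]
    if (j %in% knn_i || i %in% knn_j)
      S[i, j] <- exp(-D2[i, j] / t)
  }
  S
}
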