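test_that("Gram matrices match kernel closed forms", {
  # linear kernel on a reference with orthonormal rows -> Kcc = I
  Q <- t(orthonormal_cols(8, 4, seed = 1))   # 4 spots x 8 genes, orthonormal
  bg <- spatial_dataset(Q[1:2, , drop = FALSE], layer = "standardized")
  tg <- spatial_dataset(Q[3:4, , drop = FALSE], layer = "standardized")
  km <- gram_matrices(bg, tg, kernel_spec("linear"))
  expect_equal(km$Kcc, diag(4), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(km$Kct, t(km$Ktc))
  expect_equal(km$Kcb, t(km$Kbc))

  # gaussian kernel: any point with itself gives 1
  set.seed(2)
  X <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, paste0("g", 1:4)))
  ds <- spatial_dataset(X, layer = "standardized")
  kg <- gram_matrices(ds, ds, kernel_spec("gaussian", sigma = 2))
  expect_equal(unname(diag(kg$Kcc)), rep(1, 6))
  expect_true(all(kg$Kcc <= 1 + 1e-12))

  # polynomial degree 1 on two tiny vectors: x'y + 1
  x <- c(1, 2); y <- c(3, -1)
  ds1 <- spatial_dataset(rbind(x), gene_ids = c("a", "b"),
                         layer = "standardized")
  ds2 <- spatial_dataset(rbind(y), gene_ids = c("a", "b"),
                         layer = "standardized")
  kp <- gram_matrices(ds1, ds2, kernel_spec("polynomial", degree = 1))
  expect_equal(kp$Kcb[1, 1], sum(x * y) + 1)   # reference row 1 is target=x
  expect_error(kernel_spec("gaussian", sigma = 0), "sigma")
})

test_that("linear kernel with vanishing ridge matches the linear model", {
  # full-rank toy: N = 20 reference spots in 25 gene dimensions
  bg <- std_dataset(10, 25, seed = 5)
  tg <- std_dataset(10, 25, seed = 6)
  lin <- suppressMessages(
    cocost(bg, tg, eta = 1, mu1 = 0.5, mu2 = 0.5, k = 3, p = 3))
  kfit <- suppressMessages(
    cocost_kernel(bg, tg, kernel_spec("linear"), eta = 1, mu1 = 0.5,
                  mu2 = 0.5, k = 3, p = 3, rho = 1e-10))
  Zl <- cocost_transform(lin, tg)
  Zk <- cocost_kernel_transform(kfit, tg)
  expect_equal(ncol(Zk), 3)
  expect_lt(max(principal_angles(Zl, Zk)), 1e-4)
  # eigenvalues of the contrast agree between parameterizations
  expect_equal(kfit$eigenvalues, lin$eigenvalues[1:3], tolerance = 1e-6)
})

test_that("identical slices cancel in the kernel model too", {
  ds <- std_dataset(12, 6, seed = 8)
  kfit <- suppressMessages(
    cocost_kernel(ds, ds, kernel_spec("gaussian", sigma = 3), eta = 1,
                  mu1 = 0.4, mu2 = 0.4, k = 3, p = 5,
                  include_negative = TRUE))
  expect_lt(max(abs(kfit$spectrum)), 1e-6)
})

test_that("a very wide gaussian kernel collapses the contrast", {
  bg <- std_dataset(10, 5, seed = 9)
  tg <- std_dataset(10, 5, seed = 10)
  wide <- suppressMessages(
    cocost_kernel(bg, tg, kernel_spec("gaussian", sigma = 1e6), eta = 1,
                  mu1 = 0, mu2 = 0, p = 3, include_negative = TRUE))
  narrow <- suppressMessages(
    cocost_kernel(bg, tg, kernel_spec("gaussian", sigma = 2), eta = 1,
                  mu1 = 0, mu2 = 0, p = 3, include_negative = TRUE))
  expect_lt(max(abs(wide$spectrum)), 1e-2 * max(abs(narrow$spectrum)))
})

test_that("kernel transform is self-consistent on the reference set", {
  bg <- std_dataset(8, 6, seed = 11)
  tg <- std_dataset(9, 6, seed = 12)
  kfit <- suppressMessages(
    cocost_kernel(bg, tg, kernel_spec("gaussian", sigma = 4), eta = 1,
                  mu1 = 0.5, mu2 = 0.5, k = 3, p = 3))
  km <- gram_matrices(bg, tg, kernel_spec("gaussian", sigma = 4))
  training <- km$Kcc %*% kfit$A
  Zt <- cocost_kernel_transform(kfit, tg)
  Zb <- cocost_kernel_transform(kfit, bg)
  expect_equal(unname(rbind(Zt, Zb)), unname(training), tolerance = 1e-10)
  # a duplicated reference spot maps to the same embedding row
  dup <- spatial_dataset(as.matrix(tg$expr)[c(1, 1), ],
                         gene_ids = tg$gene_ids, spot_ids = c("d1", "d2"),
                         layer = "standardized")
  Zd <- cocost_kernel_transform(kfit, dup)
  expect_equal(Zd[1, ], Zd[2, ])
  expect_equal(unname(Zd[1, ]), unname(Zt[1, ]))
})

test_that("generalized eigen-residual is small and rho shrinks eigenvalues", {
  bg <- std_dataset(12, 8, seed = 13)
  tg <- std_dataset(12, 8, seed = 14)
  spec <- kernel_spec("polynomial", degree = 2)
  top <- c()
  for (rho in c(0.001, 0.01, 0.1, 1)) {
    kfit <- suppressMessages(
      cocost_kernel(bg, tg, spec, eta = 1, mu1 = 0.3, mu2 = 0.3, k = 3,
                    p = 4, rho = rho, include_negative = TRUE))
    km <- gram_matrices(bg, tg, spec)
    gb <- suppressMessages(build_knn_affinity(as.matrix(bg$expr), 3, kfit$t_b))
    gt <- suppressMessages(build_knn_affinity(as.matrix(tg$expr), 3, kfit$t_t))
    Hb <- laplacian_filter(normalized_laplacian(gb), 0.3)$H
    Ht <- laplacian_filter(normalized_laplacian(gt), 0.3)$H
    M <- km$Kct %*% Ht %*% km$Ktc - km$Kcb %*% Hb %*% km$Kbc
    M <- (M + t(M)) / 2
    B <- km$Kcc + diag(rho, nrow(km$Kcc))
    R <- M %*% kfit$A - B %*% kfit$A %*% diag(kfit$eigenvalues, 4)
    expect_lt(max(abs(R)), 1e-6)
    # Kcc-normalization: diag(A' Kcc A) = 1
    expect_equal(unname(colSums(kfit$A * (km$Kcc %*% kfit$A))), rep(1, 4),
                 tolerance = 1e-8)
    top <- c(top, kfit$spectrum[1])
  }
  expect_true(all(diff(top) <= 1e-10))
})
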