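#' Kernel specification
#'
#' Describes the reproducing-kernel used by the nonlinear model. Supported
#' types: \code{"linear"} (\code{x'y}), \code{"polynomial"}
#' (\code{(x'y + 1)^degree}), \code{"gaussian"}
#' (\code{exp(-||x - y||^2 / sigma^2)}), \code{"sigmoid"}
#' (\code{x'y + gamma}; note this affine form is what the printed formula
#' states — it yields a rank-deficient, PSD-up-to-centering Gram matrix),
#' and \code{"tanh"} (\code{tanh(x'y + gamma)}, the conventional sigmoid
#' kernel, offered as an alternative).
#'
#' @param type Kernel type.
#' @param degree Polynomial degree (default 2).
#' @param sigma Gaussian bandwidth, \code{> 0} (default 1).
#' @param gamma Offset for sigmoid/tanh (default 1).
#' @return An object of class \code{kernel_spec}.
#' @export
kernel_spec <- function(type = c("linear", "polynomial", "gaussian",
                                 "sigmoid", "tanh"),
                        degree = 2, sigma = 1, gamma = 1) {
  type <- match.arg(type)
  if (type == "gaussian" && sigma <= 0) stop("sigma must be > 0")
  if (type == "polynomial" && degree < 1) stop("degree must be >= 1")
  structure(list(type = type, degree = degree, sigma = sigma, gamma = gamma),
            class = "kernel_spec")
}

# Pairwise kernel evaluations: rows of X vs rows of Y.
kernel_matrix <- function(X, Y, spec) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  G <- tcrossprod(X, Y)
  switch(spec$type,
         linear = G,
         polynomial = (G + 1)^spec$degree,
         gaussian = {
           d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * G
           d2[d2 < 0] <- 0
           exp(-d2 / spec$sigma^2)
         },
         sigmoid = G + spec$gamma,
         tanh = tanh(G + spec$gamma))
}

#' Gram matrices for the kernel contrastive model
#'
#' Evaluates the kernel between the combined reference set (target spots
#' first, then background spots) and each slice. \code{Kcc} is the full
#' N x N reference Gram matrix; \code{Kct}/\code{Kcb} are its blocks
#' against the target and background slices, with \code{Ktc = t(Kct)} and
#' \code{Kbc = t(Kcb)}.
#'
#' @param background,target Standardized \code{spatial_dataset} objects
#'   on a shared gene namespace.
#' @param kernel A \code{\link{kernel_spec}}.
#' @return List with \code{Kcc}, \code{Kct}, \code{Ktc}, \code{Kcb},
#'   \code{Kbc} and the reference matrix \code{reference} (N x genes).
#' @export
gram_matrices <- function(background, target, kernel = kernel_spec()) {
  background <- .as_standardized(background, "background")
  target <- .as_standardized(target, "target")
  if (!identical(background$gene_ids, target$gene_ids))
    stop("gene namespaces differ; run align_genes() first")
  Xt <- expr_matrix(target)
  Xb <- expr_matrix(background)
  Q <- rbind(Xt, Xb)   # reference: target spots first, then background
  Kcc <- kernel_matrix(Q, Q, kernel)
  Kcc <- (Kcc + t(Kcc)) / 2
  Kct <- kernel_matrix(Q, Xt, kernel)
  Kcb <- kernel_matrix(Q, Xb, kernel)
  list(Kcc = Kcc, Kct = Kct, Ktc = t(Kct), Kcb = Kcb, Kbc = t(Kcb),
       reference = Q)
}

#' Fit the kernelized contrastive model
#'
#' Nonlinear analogue of \code{\link{cocost}}: the projection lives in the
#' kernel feature space and is parameterized by an N x p coefficient
#' matrix \code{A} over the combined reference spots (N = target +
#' background spots). \code{A} solves the generalized symmetric
#' eigenproblem
#' \deqn{(K_{ct} H_t K_{tc} - \eta K_{cb} H_b K_{bc}) A
#'       = (K_{cc} + \rho I) A \Lambda}
#' for the p algebraically largest eigenvalues, where the ridge
#' \code{rho > 0} guards against a singular Gram matrix. Columns of
#' \code{A} are scaled so that \code{diag(A' Kcc A) = 1}. Graphs and
#' filters are built in input space, exactly as in the linear model.
#'
#' @inheritParams cocost
#' @param kernel A \code{\link{kernel_spec}}.
#' @param rho Ridge constant \code{>= 0}; default
#'   \code{1e-3 * mean(diag(Kcc))}.
#' @return An object of class \code{cocost_kernel_model}: list with
#'   \code{A} (N x p), \code{eigenvalues}, \code{spectrum},
#'   \code{reference}, \code{kernel}, \code{rho}, \code{gene_ids},
#'   \code{n_target}, \code{n_background} and the graph hyperparameters.
#' @export
cocost_kernel <- function(background, target, kernel = kernel_spec(),
                          eta = 1, mu1 = 0.5, mu2 = 0.5, k = NULL,
                          t = "auto", p = 10,
                          graph_mode = c("molecular", "spatial"),
                          rho = NULL, include_negative = FALSE) {
  graph_mode <- match.arg(graph_mode)
  background <- .as_standardized(background, "background")
  target <- .as_standardized(target, "target")
  if (!identical(background$gene_ids, target$gene_ids))
    stop("gene namespaces differ; run align_genes() first")
  if (eta < 0) stop("eta must be >= 0")
  if (is.null(k)) k <- if (graph_mode == "molecular") 15L else 6L
  N <- n_spots(background) + n_spots(target)
  if (p > N) stop("p (", p, ") exceeds the reference size (", N, ")")

  fb <- .slice_filter(background, graph_mode, k, t, mu1)
  ft <- .slice_filter(target, graph_mode, k, t, mu2)
  Hb <- fb$H
  Ht <- ft$H

  km <- gram_matrices(background, target, kernel)
  if (is.null(rho)) rho <- 1e-3 * mean(diag(km$Kcc))
  if (rho < 0) stop("rho must be >= 0")

  M <- km$Kct %*% Ht %*% km$Ktc - eta * km$Kcb %*% Hb %*% km$Kbc
  M <- (M + t(M)) / 2
  B <- km$Kcc + diag(rho, N)

  R <- tryCatch(chol(B), error = function(e)
    stop("Kcc + rho*I is numerically singular; increase rho (> 0)"))
  # whiten: solve R'^-1 M R^-1, eigendecompose, map back
  S1 <- backsolve(R, M, transpose = TRUE)        # R'^-1 M
  S2 <- backsolve(R, t(S1), transpose = TRUE)    # R'^-1 M' R^-1 (M symmetric)
  S2 <- (S2 + t(S2)) / 2
  e <- eigen(S2, symmetric = TRUE)
  A_full <- backsolve(R, e$vectors)

  keep <- seq_len(p)
  if (!include_negative) keep <- keep[e$values[keep] > 1e-10]
  A <- A_full[, keep, drop = FALSE]
  # normalize so A' Kcc A has unit diagonal
  if (ncol(A)) {
    nrm <- sqrt(pmax(colSums(A * (km$Kcc %*% A)), .Machine$double.eps))
    A <- sweep(A, 2, nrm, "/")
    for (j in seq_len(ncol(A))) {
      i <- which.max(abs(A[, j]))
      if (A[i, j] < 0) A[, j] <- -A[, j]
    }
    colnames(A) <- paste0("CC", seq_len(ncol(A)))
  }

  structure(list(A = A, eigenvalues = e$values[keep], spectrum = e$values,
                 reference = km$reference, kernel = kernel, rho = rho,
                 gene_ids = target$gene_ids,
                 n_target = n_spots(target),
                 n_background = n_spots(background),
                 eta = eta, mu1 = mu1, mu2 = mu2, k = as.integer(k),
                 t_b = fb$t, t_t = ft$t, graph_mode = graph_mode),
            class = "cocost_kernel_model")
}

#' @export
print.cocost_kernel_model <- function(x, ...) {
  cat(sprintf(paste0("cocost_kernel_model: %s kernel, N = %d reference ",
                     "spots -> %d components (eta = %.3g, rho = %.3g)\n"),
              x$kernel$type, nrow(x$A), ncol(x$A), x$eta, x$rho))
  invisible(x)
}

#' Project a slice with a kernel contrastive model
#'
#' Evaluates the kernel between the new spots and the stored reference set
#' and applies the coefficient matrix: \code{Z = K(ds, reference) A}.
#' Transforming the reference spots themselves reproduces the training
#' embedding.
#'
#' @param model A \code{cocost_kernel_model}.
#' @param ds A standardized \code{spatial_dataset} (or spots-by-genes
#'   matrix) on the model's gene namespace.
#' @return Numeric matrix, spots x p.
#' @export
cocost_kernel_transform <- function(model, ds) {
  stopifnot(inherits(model, "cocost_kernel_model"))
  ds <- .as_standardized(ds, "ds")
  X <- .match_model_genes(expr_matrix(ds), model$gene_ids)
  K <- kernel_matrix(X, model$reference, model$kernel)
  Z <- K %*% model$A
  rownames(Z) <- ds$spot_ids
  Z
}
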