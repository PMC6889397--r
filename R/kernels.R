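#' The gamma grid used for the RBF kernel bank
#'
#' Six bandwidths, `2^-14` through `2^-19`, applied to every view so that no
#' single bandwidth has to be chosen a priori.
#' @export
default_gammas <- function() 2^-(14:19)

#' RBF Gram matrix of one view
#'
#' `K(x, y) = exp(-gamma * ||x - y||^2)` between sample rows of `X`. The
#' diagonal is exactly 1 and entries lie in (0, 1].
#'
#' @param X numeric matrix, samples x features.
#' @param gamma positive bandwidth.
#' @param view view label stored on the result.
#' @return An object of class `GramMatrix`: list of `values` (n x n), `view`,
#'   `gamma`.
#' @export
rbf_gram <- function(X, gamma, view = "view") {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("rbf_gram: non-finite input")
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    stop("rbf_gram: gamma must be a positive scalar")
  }
  d2 <- squared_distances(X)
  K <- exp(-gamma * d2)
  diag(K) <- 1
  K <- (K + t(K)) / 2
  gram_matrix(K, view = view, gamma = gamma)
}

# pairwise squared Euclidean distances between rows, clipped at 0
squared_distances <- function(X) {
  sq <- rowSums(X^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  d2
}

#' @rdname rbf_gram
#' @param values symmetric n x n kernel matrix (any PSD kernel, not only RBF).
#' @export
gram_matrix <- function(values, view = "view", gamma = NA_real_) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("gram_matrix: matrix must be square")
  if (max(abs(values - t(values))) > 1e-10) stop("gram_matrix: matrix not symmetric")
  structure(list(values = values, view = view, gamma = gamma),
            class = "GramMatrix")
}

#' Build the per-view RBF kernel bank
#'
#' One Gram matrix per (view, gamma) pair, in view-major, gamma-minor order;
#' all downstream weight vectors follow this bank order. Features are used
#' as-is (log2 values); optional per-gene standardization is off by default.
#'
#' @param data a [multiview_dataset()].
#' @param gammas positive bandwidth grid; defaults to [default_gammas()].
#' @param standardize logical; scale each gene to zero mean / unit variance
#'   before the kernel (default `FALSE`).
#' @return An object of class `KernelBank`: `kernels` (list of `GramMatrix`),
#'   `views`, `n_samples`, `samples`.
#' @export
build_kernel_bank <- function(data, gammas = default_gammas(), standardize = FALSE) {
  stopifnot(inherits(data, "MultiViewDataset"))
  if (length(gammas) == 0 || any(gammas <= 0)) {
    stop("build_kernel_bank: gammas must be a nonempty positive vector")
  }
  kernels <- list()
  for (v in data$views) {
    if (length(v$genes) == 0) {
      stop(sprintf("build_kernel_bank: view '%s' has zero features", v$name))
    }
    X <- v$values
    if (standardize) {
      X <- scale(X)
      X[, attr(X, "scaled:scale") == 0] <- 0
    }
    d2 <- squared_distances(X)
    for (g in gammas) {
      K <- exp(-g * d2)
      diag(K) <- 1
      kernels[[length(kernels) + 1L]] <- gram_matrix((K + t(K)) / 2,
                                                     view = v$name, gamma = g)
    }
  }
  kernel_bank(kernels)
}

#' @rdname build_kernel_bank
#' @param kernels list of `GramMatrix` objects over one shared sample set.
#' @export
kernel_bank <- function(kernels) {
  if (length(kernels) == 0) stop("kernel_bank: empty kernel list")
  n <- nrow(kernels[[1L]]$values)
  for (k in kernels) {
    if (!inherits(k, "GramMatrix") || nrow(k$values) != n) {
      stop("kernel_bank: all kernels must be GramMatrix objects of equal dimension")
    }
  }
  views <- unique(vapply(kernels, function(k) k$view, character(1)))
  structure(list(kernels = kernels, views = views, n_samples = n),
            class = "KernelBank")
}

#' @export
print.KernelBank <- function(x, ...) {
  cat(sprintf("KernelBank: %d kernels over %d view(s), n = %d\n",
              length(x$kernels), length(x$views), x$n_samples))
  invisible(x)
}

#' Weighted composite kernel
#'
#' Combines the bank into `Ktilde = sum_v w_v^p K^(v)`. Weights live on the
#' simplex (nonnegative, summing to 1, one per kernel in bank order); the
#' exponent `p >= 1` controls how sparse the learned weights become.
#'
#' @param bank a [kernel_bank()].
#' @param weights nonnegative weights summing to 1, one per kernel.
#' @param p sparsity exponent, `>= 1`.
#' @return An object of class `CompositeKernel`: `values`, `weights`, `p`.
#' @export
composite_kernel <- function(bank, weights, p) {
  stopifnot(inherits(bank, "KernelBank"))
  if (length(weights) != length(bank$kernels)) {
    stop("composite_kernel: one weight per kernel required")
  }
  if (any(weights < 0)) stop("composite_kernel: negative weight")
  if (abs(sum(weights) - 1) > 1e-6) stop("composite_kernel: weights must sum to 1")
  if (!is.numeric(p) || length(p) != 1 || p < 1) stop("composite_kernel: p must be >= 1")
  n <- bank$n_samples
  values <- matrix(0, n, n)
  wp <- weights^p
  for (i in seq_along(bank$kernels)) {
    if (wp[i] > 0) values <- values + wp[i] * bank$kernels[[i]]$values
  }
  structure(list(values = values, weights = weights, p = p),
            class = "CompositeKernel")
}

#' Kernel-induced distance matrix
#'
#' Feature-space Euclidean distance implied by a kernel:
#' `d(i, j) = sqrt(max(0, K_ii + K_jj - 2 K_ij))`. Floating-point negatives
#' under the root are clipped at zero.
#'
#' @param K a `CompositeKernel`, `GramMatrix`, or plain symmetric matrix.
#' @return n x n symmetric distance matrix with zero diagonal.
#' @export
kernel_distance <- function(K) {
  V <- if (is.matrix(K)) K else K$values
  d2 <- outer(diag(V), diag(V), "+") - 2 * V
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Serialize / load a kernel bank
#'
#' Writes each Gram matrix as a TSV file plus a `manifest.json` recording view,
#' gamma and bank order; [read_kernel_bank()] restores the bank.
#'
#' @param bank a [kernel_bank()].
#' @param dir directory (created if absent).
#' @export
write_kernel_bank <- function(bank, dir) {
  stopifnot(inherits(bank, "KernelBank"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(n_samples = bank$n_samples, kernels = list())
  for (i in seq_along(bank$kernels)) {
    k <- bank$kernels[[i]]
    fname <- sprintf("kernel_%03d.tsv", i)
    utils::write.table(format(k$values, digits = 17, trim = TRUE),
                       file.path(dir, fname), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    manifest$kernels[[i]] <- list(file = fname, view = k$view, gamma = k$gamma)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_kernel_bank
#' @export
read_kernel_bank <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  kernels <- lapply(manifest$kernels, function(m) {
    vals <- as.matrix(utils::read.table(file.path(dir, m$file), sep = "\t"))
    dimnames(vals) <- NULL
    gram_matrix(vals, view = m$view,
                gamma = if (is.null(m$gamma)) NA_real_ else m$gamma)
  })
  kernel_bank(kernels)
}
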