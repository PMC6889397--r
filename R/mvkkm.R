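#' MVKKM configuration
#'
#' @param k cluster count, `>= 2`.
#' @param p sparsity exponent, strictly `> 1` (at `p = 1` the weight update is
#'   winner-take-all and degenerates to single-kernel clustering).
#' @param max_iter maximum alternating iterations per restart.
#' @param tol relative objective-change convergence threshold.
#' @param n_restarts number of random restarts; the restart with the lowest
#'   final objective is returned.
#' @param seed integer seed for the restarts' random label initializations.
#' @return list of class `MVKKMConfig`.
#' @export
mvkkm_config <- function(k, p = 1.5, max_iter = 100, tol = 1e-8,
                         n_restarts = 30, seed = 1L) {
  if (!is.numeric(k) || k < 2) stop("mvkkm_config: k must be >= 2")
  if (!is.numeric(p) || p <= 1) stop("mvkkm_config: p must be > 1")
  structure(list(k = as.integer(k), p = p, max_iter = as.integer(max_iter),
                 tol = tol, n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "MVKKMConfig")
}

#' Within-cluster distortion of one kernel
#'
#' Kernel-space within-cluster scatter,
#' `D = sum_c [ sum_{i in c} K_ii - (1/|c|) sum_{i,j in c} K_ij ]`,
#' the per-kernel building block of the MVKKM objective.
#'
#' @param K a `GramMatrix`, `CompositeKernel`, or plain kernel matrix.
#' @param labels integer cluster assignment (1-based); every cluster nonempty.
#' @return nonnegative scalar.
#' @export
view_distortion <- function(K, labels) {
  V <- if (is.matrix(K)) K else K$values
  labels <- as.integer(labels)
  if (length(labels) != nrow(V)) stop("view_distortion: labels do not match kernel size")
  D <- 0
  for (c in unique(labels)) {
    ix <- which(labels == c)
    if (length(ix) == 0) stop("view_distortion: empty cluster")
    D <- D + sum(diag(V)[ix]) - sum(V[ix, ix]) / length(ix)
  }
  max(D, 0)
}

#' Closed-form kernel weight update
#'
#' Minimizes `sum_v w_v^p D_v` over the probability simplex:
#' `w_v` proportional to `D_v^(-1/(p-1))` (KKT stationarity). Weights are
#' strictly decreasing in distortion. If any distortion is exactly zero, all
#' weight is split uniformly among the zero-distortion kernels (the limit of
#' the closed form) and a message flags the degenerate case.
#'
#' @param distortions nonnegative per-kernel distortions.
#' @param p sparsity exponent, `> 1`.
#' @return weight vector on the simplex, in the input order.
#' @export
update_weights <- function(distortions, p) {
  if (!is.numeric(p) || length(p) != 1 || p <= 1) stop("update_weights: p must be > 1")
  if (any(distortions < 0)) stop("update_weights: negative distortion")
  zero <- distortions == 0
  if (any(zero)) {
    message("update_weights: zero-distortion kernel(s); weight split among them")
    w <- as.numeric(zero) / sum(zero)
    return(w)
  }
  u <- distortions^(-1 / (p - 1))
  u / sum(u)
}

#' One batch assignment pass of kernel k-means
#'
#' With clusters frozen from the input labels, each sample moves to the
#' cluster minimizing its kernel-space distance to the cluster centroid:
#' `K_ii - (2/|c|) sum_{j in c} K_ij + (1/|c|^2) sum_{j,l in c} K_jl`.
#' Ties are broken toward the lowest cluster index. The composite distortion
#' never increases across a pass.
#'
#' @param K `CompositeKernel`, `GramMatrix` or kernel matrix.
#' @param labels current assignment (1-based), every cluster in `1..k` nonempty.
#' @param k number of clusters; defaults to `max(labels)`.
#' @return new integer assignment.
#' @export
kernel_kmeans_step <- function(K, labels, k = max(labels)) {
  V <- if (is.matrix(K)) K else K$values
  labels <- as.integer(labels)
  n <- nrow(V)
  dmat <- matrix(Inf, n, k)
  dV <- diag(V)
  for (c in seq_len(k)) {
    ix <- which(labels == c)
    if (length(ix) == 0) next
    s1 <- rowSums(V[, ix, drop = FALSE])
    s2 <- sum(V[ix, ix])
    dmat[, c] <- dV - 2 * s1 / length(ix) + s2 / length(ix)^2
  }
  # argmin with ties to the lowest cluster index
  max.col(-dmat, ties.method = "first")
}

# move the sample farthest from its own centroid into each empty cluster
repair_empty_clusters <- function(V, labels, k) {
  labels <- as.integer(labels)
  for (c in seq_len(k)) {
    if (any(labels == c)) next
    dself <- rep(-Inf, length(labels))
    for (cc in unique(labels)) {
      ix <- which(labels == cc)
      if (length(ix) < 2) next  # don't empty a singleton
      s1 <- rowSums(V[ix, ix, drop = FALSE])
      s2 <- sum(V[ix, ix])
      dself[ix] <- diag(V)[ix] - 2 * s1 / length(ix) + s2 / length(ix)^2
    }
    far <- which.max(dself)
    labels[far] <- c
  }
  labels
}

#' Fit multi-view kernel k-means
#'
#' Alternates two steps until convergence: (i) kernel k-means on the current
#' weighted composite kernel until the assignment is stable, and (ii) the
#' closed-form re-weighting of kernels by inverse distortion. Each restart
#' starts from uniform weights and a seeded uniform-random assignment; the
#' restart with the lowest final composite distortion wins. The objective
#' `sum_v w_v^p D_v` is non-increasing within every restart.
#'
#' @param bank a [kernel_bank()].
#' @param config an [mvkkm_config()].
#' @param init_labels optional initial assignment (forces `n_restarts = 1`).
#' @return An object of class `MVKKMResult`: `labels`, `weights` (bank order),
#'   `view_weights`, `objective`, `objective_trace`, `restart_objectives`,
#'   `k`, `p`, `converged`, `iterations`.
#' @export
mvkkm_fit <- function(bank, config, init_labels = NULL) {
  stopifnot(inherits(bank, "KernelBank"), inherits(config, "MVKKMConfig"))
  n <- bank$n_samples
  k <- config$k
  if (k > n) stop("mvkkm_fit: k exceeds the number of samples")
  n_restarts <- if (is.null(init_labels)) config$n_restarts else 1L
  rng <- make_rng(config$seed)

  best <- NULL
  restart_objectives <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    labels <- if (is.null(init_labels)) {
      random_assignment(n, k, rng)
    } else {
      as.integer(init_labels)
    }
    fit <- mvkkm_single_run(bank, labels, k, config$p, config$max_iter, config$tol)
    restart_objectives[r] <- fit$objective
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }

  view_of <- vapply(bank$kernels, function(x) x$view, character(1))
  vw <- tapply(best$weights, factor(view_of, levels = bank$views), sum)
  structure(list(labels = best$labels, weights = best$weights,
                 view_weights = stats::setNames(as.numeric(vw), bank$views),
                 objective = best$objective,
                 objective_trace = best$trace,
                 restart_objectives = restart_objectives,
                 k = k, p = config$p, converged = best$converged,
                 iterations = best$iterations),
            class = "MVKKMResult")
}

mvkkm_single_run <- function(bank, labels, k, p, max_iter, tol) {
  m <- length(bank$kernels)
  weights <- rep(1 / m, m)
  trace <- numeric(0)
  obj <- Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Kc <- composite_kernel(bank, weights, p)
    # assignment step: iterate batch passes to a stable labeling
    labels_stable <- FALSE
    for (pass in seq_len(max_iter)) {
      new_labels <- kernel_kmeans_step(Kc, labels, k)
      new_labels <- repair_empty_clusters(Kc$values, new_labels, k)
      if (identical(new_labels, labels)) { labels_stable <- TRUE; break }
      labels <- new_labels
    }
    # weight step
    distortions <- vapply(bank$kernels, view_distortion, numeric(1), labels = labels)
    weights <- suppressMessages(update_weights(distortions, p))
    new_obj <- sum(weights^p * distortions)
    trace <- c(trace, new_obj)
    rel_change <- if (is.finite(obj) && obj > 0) (obj - new_obj) / obj else Inf
    done <- labels_stable && is.finite(obj) && abs(rel_change) < tol
    obj <- new_obj
    if (done) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  list(labels = labels, weights = weights, objective = obj, trace = trace,
       converged = converged, iterations = iter)
}

# local RNG stream so fits do not disturb the global seed
make_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    s
  })
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  eval(expr)
}

# seeded uniform-random assignment guaranteed to hit every cluster
random_assignment <- function(n, k, rng) {
  with_rng(rng, {
    labels <- sample.int(k, n, replace = TRUE)
    miss <- setdiff(seq_len(k), unique(labels))
    if (length(miss)) labels[sample.int(n, length(miss))] <- miss
    labels
  })
}

#' @export
print.MVKKMResult <- function(x, ...) {
  cat(sprintf("MVKKMResult: k = %d, p = %.2f, objective = %.6g (%s)\n",
              x$k, x$p, x$objective,
              if (x$converged) "converged" else "max_iter reached"))
  cat("cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  cat("view weights:\n")
  print(round(x$view_weights, 4))
  invisible(x)
}

#' Per-view sums of learned kernel weights
#'
#' With several kernels per view (one per gamma), the per-kernel weights are
#' summed within each view; the sums total 1 and measure each data type's
#' contribution to the clustering.
#'
#' @param result an [mvkkm_fit()] result.
#' @param bank the [kernel_bank()] the result was fitted on.
#' @return named numeric vector, one sum per view.
#' @export
aggregate_view_weights <- function(result, bank) {
  stopifnot(inherits(result, "MVKKMResult"), inherits(bank, "KernelBank"))
  if (length(result$weights) != length(bank$kernels)) {
    stop("aggregate_view_weights: result does not match bank")
  }
  view_of <- vapply(bank$kernels, function(x) x$view, character(1))
  vw <- tapply(result$weights, factor(view_of, levels = bank$views), sum)
  stats::setNames(as.numeric(vw), bank$views)
}

#' Serialize an MVKKM result to JSON
#' @param result an `MVKKMResult`.
#' @param path output path.
#' @export
write_mvkkm_result <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
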