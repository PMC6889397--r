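#' Mean silhouette coefficient
#'
#' Per-sample score `(b_i - a_i) / max(a_i, b_i)` where `a_i` is the mean
#' distance to the sample's own-cluster co-members and `b_i` the minimum over
#' other clusters of the mean distance to that cluster's members; samples in
#' singleton clusters score 0 by convention. The mean over all samples is
#' returned; it lies in `[-1, 1]`.
#'
#' @param dist symmetric n x n distance matrix.
#' @param labels cluster assignment with at least two nonempty clusters.
#' @return scalar mean silhouette.
#' @export
mean_silhouette <- function(dist, labels) {
  labels <- as.integer(labels)
  n <- nrow(dist)
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("mean_silhouette: need at least two clusters")
  sizes <- table(factor(labels, levels = cl))
  # mean distance from each sample to each cluster
  md <- vapply(cl, function(c) rowMeans(dist[, labels == c, drop = FALSE]),
               numeric(n))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- match(labels[i], cl)
    sz <- sizes[own]
    if (sz == 1) { s[i] <- 0; next }
    a <- md[i, own] * sz / (sz - 1)  # exclude self (self-distance is 0)
    b <- min(md[i, -own])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Dunn index
#'
#' Minimum between-cluster distance divided by the maximum within-cluster
#' diameter. Larger is better; a zero maximum diameter (all clusters
#' singletons or duplicated points) yields `Inf`.
#'
#' @inheritParams mean_silhouette
#' @return nonnegative scalar (possibly `Inf`).
#' @export
dunn_index <- function(dist, labels) {
  labels <- as.integer(labels)
  cl <- sort(unique(labels))
  if (length(cl) < 2) stop("dunn_index: need at least two clusters")
  min_between <- Inf
  max_diam <- 0
  for (a in seq_along(cl)) {
    ia <- which(labels == cl[a])
    if (length(ia) > 1) {
      max_diam <- max(max_diam, max(dist[ia, ia]))
    }
    for (b in seq_along(cl)) {
      if (b <= a) next
      ib <- which(labels == cl[b])
      min_between <- min(min_between, min(dist[ia, ib]))
    }
  }
  if (max_diam == 0) return(Inf)
  min_between / max_diam
}

#' Connectivity index
#'
#' For each sample, its `L` nearest neighbors are inspected; the j-th nearest
#' neighbor adds a penalty `1/j` when it lies in a different cluster. Lower is
#' better; 0 means every sample's `L`-neighborhood is cluster-pure.
#'
#' @inheritParams mean_silhouette
#' @param L neighborhood size, `0 < L < n` (default 10).
#' @return nonnegative scalar.
#' @export
connectivity <- function(dist, labels, L = 10) {
  labels <- as.integer(labels)
  n <- nrow(dist)
  if (L <= 0) stop("connectivity: L must be positive")
  L <- min(L, n - 1)
  total <- 0
  for (i in seq_len(n)) {
    nn <- order(dist[i, -i])  # indices into the vector without i
    others <- seq_len(n)[-i]
    foreign <- labels[others[nn[seq_len(L)]]] != labels[i]
    total <- total + sum((1 / seq_len(L))[foreign])
  }
  total
}

#' Exact weighted rank aggregation
#'
#' Finds the consensus ordering minimizing the weighted Spearman footrule
#' distance `sum_m importance_m * sum_c |pos(c) - pos_m(c)|` to the input
#' rankings, by exhaustive enumeration over all permutations of the candidate
#' set (at most 8 candidates). Ties in the objective are broken toward the
#' lexicographically smallest candidate sequence.
#'
#' @param rankings list of orderings (vectors, best candidate first) of one
#'   shared candidate set.
#' @param importance per-ranking weights; default equal.
#' @return the consensus ordering (same type as the inputs).
#' @export
rank_aggregate <- function(rankings, importance = rep(1, length(rankings))) {
  if (length(rankings) == 0) stop("rank_aggregate: no rankings")
  cand <- sort(rankings[[1L]])
  for (r in rankings) {
    if (!identical(sort(r), cand)) {
      stop("rank_aggregate: rankings must permute the same candidate set")
    }
  }
  m <- length(cand)
  if (m > 8) stop("rank_aggregate: more than 8 candidates not supported")
  if (length(importance) != length(rankings)) {
    stop("rank_aggregate: one importance weight per ranking required")
  }
  # positions of each candidate in each input ranking
  pos_in <- matrix(vapply(rankings, function(r) match(cand, r), numeric(m)),
                   nrow = m)
  perms <- permutations(m)
  best_score <- Inf
  best <- NULL
  for (i in seq_len(nrow(perms))) {
    # candidate cand[j] sits at position match(j, perms[i,]) in this ordering
    pos <- match(seq_len(m), perms[i, ])
    score <- sum(importance * colSums(abs(pos - pos_in)))
    if (score < best_score - 1e-12) {
      best_score <- score
      best <- cand[perms[i, ]]
    }
  }
  best
}

# all permutations of 1..m, in lexicographic order (rows)
permutations <- function(m) {
  if (m == 1) return(matrix(1L, 1, 1))
  sub <- permutations(m - 1L)
  out <- matrix(0L, m * nrow(sub), m)
  row <- 1L
  for (first in seq_len(m)) {
    rest <- seq_len(m)[-first]
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

# score one fitted clustering on the kernel distances of its composite kernel
validity_scores <- function(bank, fit, L = 10) {
  Kc <- composite_kernel(bank, fit$weights, fit$p)
  d <- kernel_distance(Kc)
  list(k = fit$k,
       silhouette = mean_silhouette(d, fit$labels),
       dunn = dunn_index(d, fit$labels),
       connectivity = connectivity(d, fit$labels, L = L))
}

#' Select the number of clusters
#'
#' For each of `n_restarts` restarts, MVKKM is fitted once per candidate `k`;
#' each fit is scored on the kernel-induced distance of its own final composite
#' kernel by mean silhouette (maximized), Dunn (maximized) and connectivity
#' (minimized). The three per-index rankings are combined by exact weighted
#' rank aggregation and the restart votes for the top candidate. The final `k`
#' is the mode of the votes, ties broken toward the smaller `k`.
#'
#' @param bank a [kernel_bank()].
#' @param p sparsity exponent.
#' @param k_range candidate cluster counts (within `[2, n - 1]`, at most 8).
#' @param config an [mvkkm_config()]; its `n_restarts` and `seed` drive the
#'   voting; `k` is ignored.
#' @param importance weights of the three indices in the aggregation
#'   (silhouette, Dunn, connectivity); default equal.
#' @param L connectivity neighborhood size.
#' @return list of class `KSelectionReport`: `final_k`, `per_restart_choices`,
#'   `per_k_scores` (last restart's score table), `aggregated_ranking`.
#' @export
select_k <- function(bank, p, k_range, config, importance = rep(1, 3), L = 10) {
  if (length(k_range) == 0) stop("select_k: empty candidate list")
  n <- bank$n_samples
  if (any(k_range < 2 | k_range > n - 1)) {
    stop("select_k: candidates must lie in [2, n - 1]")
  }
  k_range <- sort(unique(as.integer(k_range)))
  choices <- integer(config$n_restarts)
  scores_tab <- NULL
  agg <- NULL
  for (r in seq_len(config$n_restarts)) {
    scores <- lapply(k_range, function(k) {
      cfg <- mvkkm_config(k = k, p = p, max_iter = config$max_iter,
                          tol = config$tol, n_restarts = 1,
                          seed = config$seed + 1000L * r + k)
      validity_scores(bank, mvkkm_fit(bank, cfg), L = L)
    })
    sil <- vapply(scores, `[[`, numeric(1), "silhouette")
    dun <- vapply(scores, `[[`, numeric(1), "dunn")
    con <- vapply(scores, `[[`, numeric(1), "connectivity")
    rankings <- list(k_range[order(-sil, k_range)],
                     k_range[order(-dun, k_range)],
                     k_range[order(con, k_range)])
    agg <- rank_aggregate(rankings, importance)
    choices[r] <- agg[1L]
    scores_tab <- data.frame(k = k_range, silhouette = sil,
                             dunn = dun, connectivity = con)
  }
  tab <- table(choices)
  winners <- as.integer(names(tab)[tab == max(tab)])
  structure(list(final_k = min(winners), per_restart_choices = choices,
                 per_k_scores = scores_tab, aggregated_ranking = agg),
            class = "KSelectionReport")
}

#' @export
print.KSelectionReport <- function(x, ...) {
  cat(sprintf("KSelectionReport: final k = %d (votes: %s)\n", x$final_k,
              paste(sprintf("k=%s:%d", names(table(x$per_restart_choices)),
                            as.integer(table(x$per_restart_choices))),
                    collapse = ", ")))
  print(x$per_k_scores)
  invisible(x)
}

#' Select the sparsity exponent p
#'
#' Fits MVKKM at the given `k` for each candidate `p` and returns the one whose
#' clustering maximizes mean silhouette on its composite-kernel distances; ties
#' go to the smaller `p`.
#'
#' @param bank a [kernel_bank()].
#' @param p_grid candidate exponents, e.g. `c(1.5, 2, 2.5)`.
#' @param k cluster count.
#' @param config an [mvkkm_config()] providing restarts / seed / tolerances.
#' @return list: `p` (the winner) and `scores` (silhouette per candidate).
#' @export
select_p <- function(bank, p_grid = c(1.5, 2, 2.5), k, config) {
  if (length(p_grid) == 0) stop("select_p: empty p grid")
  p_grid <- sort(p_grid)
  sil <- vapply(p_grid, function(p) {
    cfg <- mvkkm_config(k = k, p = p, max_iter = config$max_iter,
                        tol = config$tol, n_restarts = config$n_restarts,
                        seed = config$seed)
    fit <- mvkkm_fit(bank, cfg)
    validity_scores(bank, fit)$silhouette
  }, numeric(1))
  list(p = p_grid[which.max(sil)], scores = data.frame(p = p_grid, silhouette = sil))
}
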