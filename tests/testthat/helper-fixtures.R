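# shared fixtures: tiny deterministic datasets built in code

# n points per blob around given 2-D centers; returns X and labels
make_blobs <- function(centers, n_per = 10, sd = 0.2, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  X <- do.call(rbind, lapply(seq_len(k), function(c) {
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per, ncol(centers)) +
      rep(centers[c, ], each = n_per)
  }))
  list(X = X, labels = rep(seq_len(k), each = n_per))
}

# a small multi-view dataset with planted 2-cluster structure
small_cohort <- function(n = 60, seed = 7, effect = 3, noise_view = FALSE) {
  views <- list(
    view_spec("v1", n_genes = 100, n_informative = 30, effect_size = effect),
    view_spec("v2", n_genes = 100, n_informative = 30, effect_size = effect))
  if (noise_view) {
    views <- c(views, list(view_spec("noise", n_genes = 100, n_informative = 30,
                                     effect_size = effect, informative = FALSE)))
  }
  simulate_cohort(synthetic_config(
    n_samples = n, k_true = 2, cluster_proportions = c(0.5, 0.5),
    views = views, baseline_hazard = c(0.0002, 0.001), seed = seed))
}

# a tiny expression view from a plain matrix
toy_view <- function(values, name = "toy", platform = "microarray") {
  if (is.null(rownames(values))) rownames(values) <- paste0("s", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("g", seq_len(ncol(values)))
  expression_view(values, name = name, platform = platform)
}

# clinical table covering given samples with simple defaults
toy_clinical <- function(samples, os_time = NULL, os_event = NULL,
                         high_risk = NULL, mycn = 0L, age = 365, stage = 2L) {
  n <- length(samples)
  clinical_table(data.frame(
    sample = samples,
    os_event = if (is.null(os_event)) rep(1L, n) else os_event,
    os_time = if (is.null(os_time)) seq_len(n) else os_time,
    efs_event = if (is.null(os_event)) rep(1L, n) else os_event,
    efs_time = if (is.null(os_time)) seq_len(n) else os_time,
    high_risk = if (is.null(high_risk)) rep(0L, n) else high_risk,
    mycn_amplified = mycn, age = age, stage = stage))
}

# adjusted Rand index (mclust if present, else exact formula)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  sum_ij <- comb2(tab)
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  total <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / total
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# an initial partition from which stats::kmeans Lloyd runs without hitting an
# empty cluster, so the oracle trajectory is well-defined
clean_lloyd_init <- function(X, k, base_seed = 1) {
  for (s in base_seed + 0:50) {
    set.seed(s)
    init <- sample(rep(seq_len(k), length.out = nrow(X)))
    centers <- do.call(rbind, lapply(seq_len(k), function(c)
      colMeans(X[init == c, , drop = FALSE])))
    ok <- TRUE
    oracle <- withCallingHandlers(
      kmeans(X, centers = centers, algorithm = "Lloyd", iter.max = 200),
      warning = function(w) { ok <<- FALSE; invokeRestart("muffleWarning") })
    if (ok) return(list(init = init, oracle = oracle))
  }
  stop("no clean Lloyd start found")
}
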