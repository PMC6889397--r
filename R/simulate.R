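#' Specify one synthetic expression view
#'
#' @param name view label.
#' @param n_genes total genes.
#' @param n_informative genes carrying cluster-specific mean shifts
#'   (ignored for non-informative views).
#' @param effect_size SD of the cluster-mean offsets, in units of `noise_sd`.
#' @param noise_sd per-gene residual SD; for non-informative views the default
#'   (`NULL`) is variance-matched to an informative view,
#'   `sqrt(noise_sd^2 + (n_informative/n_genes) * effect_size^2)`, because a
#'   real uninformative dataset still carries full biological variance — it is
#'   merely unaligned with the subtypes.
#' @param informative logical; `FALSE` makes the view pure noise.
#' @param platform platform label.
#' @export
view_spec <- function(name, n_genes = 2000, n_informative = 100,
                      effect_size = 1, noise_sd = NULL, informative = TRUE,
                      platform = name) {
  if (n_informative > n_genes) {
    stop("view_spec: n_informative exceeds n_genes")
  }
  list(name = name, n_genes = as.integer(n_genes),
       n_informative = as.integer(n_informative),
       effect_size = effect_size, noise_sd = noise_sd,
       informative = isTRUE(informative), platform = platform)
}

#' Synthetic cohort recipe
#'
#' Defaults emulate the structure of the neuroblastoma study cohort: ~500
#' patients, two latent subtypes (65/35), three correlated informative
#' expression views (two RNA-seq normalizations and a microarray) in which a
#' tenth of the genes carry 2-SD subtype shifts (subtype signatures in this
#' disease span hundreds of strongly regulated genes), a fivefold hazard
#' contrast between subtypes, and >80% right censoring.
#'
#' @param n_samples cohort size.
#' @param k_true planted cluster count.
#' @param cluster_proportions simplex vector of length `k_true`.
#' @param views list of [view_spec()] objects.
#' @param baseline_hazard per-cluster event hazard (per day).
#' @param censoring_rate_target fraction of samples right-censored, in (0,1).
#' @param os_flip_prob,efs_flip_prob symmetric label-noise rates used to derive
#'   the binary OS/EFS endpoints from the event indicator (EFS gets the higher
#'   rate: the EFS label is less unbalanced than OS in the cohorts emulated).
#' @param hr_flip_prob noise between planted cluster and the high-risk flag.
#' @param seed integer seed for patient-level sampling; the whole generator is
#'   deterministic given it (and `signal_seed`).
#' @param signal_seed seed of the cluster-center and gene-baseline draw. Two
#'   cohorts with the same view specs and `signal_seed` but different `seed`
#'   share the same molecular signature over independent patients — the
#'   setting of cross-cohort prediction experiments.
#' @return list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_samples = 498,
                             k_true = 2,
                             cluster_proportions = c(0.65, 0.35),
                             views = list(
                               view_spec("rnaseq-mav", 2000, 200, 2),
                               view_spec("rnaseq-rpm", 2000, 200, 2),
                               view_spec("microarray", 2000, 200, 2)),
                             baseline_hazard = c(0.0002, 0.001),
                             censoring_rate_target = 0.8,
                             os_flip_prob = 0.02,
                             efs_flip_prob = 0.2,
                             hr_flip_prob = 0.1,
                             seed = 1L,
                             signal_seed = 42L) {
  if (k_true < 2) stop("synthetic_config: k_true must be >= 2")
  if (abs(sum(cluster_proportions) - 1) > 1e-8 ||
      length(cluster_proportions) != k_true) {
    stop("synthetic_config: cluster_proportions must be a simplex of length k_true")
  }
  if (censoring_rate_target <= 0 || censoring_rate_target >= 1) {
    stop("synthetic_config: censoring target must be in (0,1)")
  }
  if (length(baseline_hazard) != k_true || any(baseline_hazard <= 0)) {
    stop("synthetic_config: one positive hazard per cluster required")
  }
  structure(list(n_samples = as.integer(n_samples), k_true = as.integer(k_true),
                 cluster_proportions = cluster_proportions, views = views,
                 baseline_hazard = baseline_hazard,
                 censoring_rate_target = censoring_rate_target,
                 os_flip_prob = os_flip_prob, efs_flip_prob = efs_flip_prob,
                 hr_flip_prob = hr_flip_prob, seed = as.integer(seed),
                 signal_seed = as.integer(signal_seed)),
            class = "SyntheticConfig")
}

# draw planted labels covering every cluster
draw_labels <- function(n, proportions) {
  k <- length(proportions)
  labels <- sample.int(k, n, replace = TRUE, prob = proportions)
  miss <- setdiff(seq_len(k), unique(labels))
  if (length(miss)) labels[sample.int(n, length(miss))] <- miss
  labels
}

simulate_one_view <- function(spec, labels, sample_ids, signal_seed) {
  n <- length(labels)
  k <- max(labels)
  base_sd <- if (is.null(spec$noise_sd)) 1 else spec$noise_sd
  if (!spec$informative && is.null(spec$noise_sd)) {
    base_sd <- sqrt(1 + (spec$n_informative / spec$n_genes) * spec$effect_size^2)
  }
  # the molecular signature (gene baselines + cluster centers) is drawn from
  # its own seed so that cohorts can share it across independent patient draws
  sig_rng <- make_rng(signal_seed)
  sig <- with_rng(sig_rng, {
    gene_means <- stats::rnorm(spec$n_genes, mean = 7, sd = 2)  # log2 baseline
    noise_sd <- if (is.null(spec$noise_sd)) 1 else spec$noise_sd
    centers <- matrix(stats::rnorm(k * spec$n_informative,
                                   sd = spec$effect_size * noise_sd),
                      k, spec$n_informative)
    list(gene_means = gene_means, centers = centers)
  })
  values <- matrix(stats::rnorm(n * spec$n_genes, sd = base_sd), n, spec$n_genes)
  values <- sweep(values, 2, sig$gene_means, "+")
  if (spec$informative && spec$n_informative > 0 && spec$effect_size > 0) {
    inf_ix <- seq_len(spec$n_informative)
    values[, inf_ix] <- values[, inf_ix] + sig$centers[labels, , drop = FALSE]
  }
  rownames(values) <- sample_ids
  colnames(values) <- sprintf("gene%05d", seq_len(spec$n_genes))
  expression_view(values, name = spec$name, platform = spec$platform)
}

#' Simulate the expression views of a cohort
#'
#' Planted cluster labels are drawn from the configured proportions;
#' informative views add cluster-specific mean shifts (drawn once per cluster
#' and informative gene) on top of Gaussian noise; non-informative views are
#' pure (variance-matched) noise. Views are correlated only through the shared
#' labels. The labels are returned in the `truth` sidecar, never inside any
#' view.
#'
#' @param config a [synthetic_config()].
#' @return A [multiview_dataset()] (views only) with `truth$labels`.
#' @export
simulate_multiview <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  rng <- make_rng(config$seed)
  with_rng(rng, {
    n <- config$n_samples
    sample_ids <- sprintf("S%04d", seq_len(n))
    labels <- draw_labels(n, config$cluster_proportions)
    views <- lapply(seq_along(config$views), function(i) {
      simulate_one_view(config$views[[i]], labels = labels,
                        sample_ids = sample_ids,
                        signal_seed = config$signal_seed + i)
    })
    names(views) <- vapply(config$views, `[[`, character(1), "name")
    multiview_dataset(views, truth = list(labels = labels, config = config))
  })
}

#' Simulate cluster-linked survival with calibrated heavy censoring
#'
#' Event times are exponential with the cluster's hazard; censoring times are
#' exponential with a rate calibrated by bisection so the expected censored
#' fraction hits the target. Observed time is the minimum, event the
#' indicator.
#'
#' @param labels planted cluster labels.
#' @param config a [synthetic_config()] (hazards, censoring target).
#' @return A [survival_data()].
#' @export
simulate_survival <- function(labels, config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  hazards <- config$baseline_hazard[labels]
  rate_c <- calibrate_censoring_rate(hazards, config$censoring_rate_target)
  t_event <- stats::rexp(length(labels), rate = hazards)
  t_cens <- stats::rexp(length(labels), rate = rate_c)
  survival_data(pmin(t_event, t_cens), as.integer(t_event <= t_cens))
}

# expected censored fraction with exponential censoring at rate rc is
# mean(rc / (rc + hazard_i)); monotone increasing in rc, solved by bisection
calibrate_censoring_rate <- function(hazards, target, max_steps = 50) {
  frac <- function(rc) mean(rc / (rc + hazards))
  lo <- min(hazards) * 1e-9
  hi <- max(hazards) * 1e9
  if (frac(lo) > target || frac(hi) < target) {
    stop("simulate_survival: censoring target unattainable")
  }
  for (step in seq_len(max_steps)) {
    mid <- sqrt(lo * hi)
    if (frac(mid) < target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

flip_binary <- function(x, prob) {
  flip <- stats::runif(length(x)) < prob
  ifelse(flip, 1L - x, x)
}

#' Simulate a full cohort
#'
#' Assembles expression views, survival outcomes, binary OS/EFS endpoints
#' (event indicator with flip noise), a high-risk flag (planted cluster with
#' flip noise), MYCN status (correlated with the high-risk flag, with some
#' missingness as in real cohorts) and weakly cluster-correlated age/stage
#' covariates into a [multiview_dataset()] with a ground-truth sidecar.
#'
#' @param config a [synthetic_config()].
#' @return A `MultiViewDataset` with `clinical` and `truth` attached.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  data <- simulate_multiview(config)
  labels <- data$truth$labels
  rng <- make_rng(config$seed + 1L)
  clinical <- with_rng(rng, {
    surv <- simulate_survival(labels, config)
    n <- config$n_samples
    # efs emulated as a noisier, earlier endpoint on the same latent process
    efs_time <- surv$time * stats::runif(n, 0.6, 1)
    os_event <- flip_binary(surv$event, config$os_flip_prob)
    efs_event <- flip_binary(surv$event, config$efs_flip_prob)
    worst <- which.max(config$baseline_hazard)
    high_risk <- flip_binary(as.integer(labels == worst), config$hr_flip_prob)
    mycn <- flip_binary(high_risk, 0.25)
    mycn[stats::runif(n) < 0.02] <- NA_integer_
    age <- round(stats::rgamma(n, shape = 1.5, scale = 400) +
                   200 * (labels == worst))
    stage_shift <- as.integer(labels == worst)
    stage <- pmin(4L, pmax(1L, stats::rpois(n, lambda = 1 + stage_shift) + 1L))
    clinical_table(data.frame(
      sample = data$views[[1L]]$samples,
      os_event = os_event, os_time = surv$time,
      efs_event = efs_event, efs_time = efs_time,
      high_risk = high_risk, mycn_amplified = mycn,
      age = age, stage = stage))
  })
  data$clinical <- clinical
  data$truth$os <- survival_data(clinical$os_time, clinical$os_event)
  data
}

#' Write a synthetic cohort to disk
#'
#' TSV per view, CSV clinical table, and the ground truth as a separate JSON
#' sidecar (never mixed into the pipeline inputs).
#'
#' @param data a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @export
write_cohort <- function(data, dir) {
  stopifnot(inherits(data, "MultiViewDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in data$views) {
    write_expression(v, file.path(dir, paste0(v$name, ".tsv")))
  }
  if (!is.null(data$clinical)) {
    write_clinical(data$clinical, file.path(dir, "clinical.csv"))
  }
  if (!is.null(data$truth)) {
    jsonlite::write_json(list(labels = data$truth$labels),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
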