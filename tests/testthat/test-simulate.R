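test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- synthetic_config(n_samples = 30, seed = 5,
                          views = list(view_spec("v", 50, 10, 2)),
                          k_true = 2, cluster_proportions = c(0.5, 0.5),
                          baseline_hazard = c(0.001, 0.005))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$views[[1]]$values, b$views[[1]]$values)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth$labels, b$truth$labels)
  # a different seed changes the data
  c2 <- simulate_cohort(synthetic_config(n_samples = 30, seed = 6,
                          views = list(view_spec("v", 50, 10, 2)),
                          k_true = 2, cluster_proportions = c(0.5, 0.5),
                          baseline_hazard = c(0.001, 0.005)))
  expect_false(identical(a$views[[1]]$values, c2$views[[1]]$values))
})

test_that("cohorts sharing signal_seed share cluster centers across patients", {
  mk <- function(seed) simulate_multiview(synthetic_config(
    n_samples = 200, seed = seed, signal_seed = 99,
    views = list(view_spec("v", 100, 40, 3)),
    k_true = 2, cluster_proportions = c(0.5, 0.5),
    baseline_hazard = c(0.001, 0.005)))
  a <- mk(1); b <- mk(2)
  # per-cluster means of the informative genes line up across cohorts
  ma <- colMeans(a$views[[1]]$values[a$truth$labels == 1, 1:40]) -
        colMeans(a$views[[1]]$values[a$truth$labels == 2, 1:40])
  mb <- colMeans(b$views[[1]]$values[b$truth$labels == 1, 1:40]) -
        colMeans(b$views[[1]]$values[b$truth$labels == 2, 1:40])
  expect_gt(cor(ma, mb), 0.9)
})

test_that("zero effect size yields views carrying no cluster signal", {
  cfg <- synthetic_config(n_samples = 400, seed = 3,
                          views = list(view_spec("v", 60, 30, 0)),
                          k_true = 2, cluster_proportions = c(0.5, 0.5),
                          baseline_hazard = c(0.001, 0.005))
  d <- simulate_multiview(cfg)
  diffs <- colMeans(d$views[[1]]$values[d$truth$labels == 1, ]) -
           colMeans(d$views[[1]]$values[d$truth$labels == 2, ])
  # standardized mean differences behave like pure noise
  expect_lt(max(abs(diffs)), 4 / sqrt(100))
})

test_that("config validation rejects impossible recipes", {
  expect_error(view_spec("v", n_genes = 10, n_informative = 20), "exceeds")
  expect_error(synthetic_config(k_true = 1), "k_true")
  expect_error(synthetic_config(cluster_proportions = c(0.5, 0.4)), "simplex")
  expect_error(synthetic_config(censoring_rate_target = 1.2), "\\(0,1\\)")
  expect_error(synthetic_config(baseline_hazard = c(1, -1)), "positive hazard")
})

test_that("censoring calibration hits the target on large cohorts", {
  cfg <- synthetic_config(n_samples = 2000, seed = 8,
                          views = list(view_spec("v", 10, 2, 1)),
                          k_true = 2, cluster_proportions = c(0.5, 0.5),
                          baseline_hazard = c(0.0002, 0.001),
                          censoring_rate_target = 0.8)
  set.seed(8)
  labels <- sample(1:2, 2000, replace = TRUE)
  sv <- simulate_survival(labels, cfg)
  censored_frac <- mean(sv$event == 0)
  expect_gte(censored_frac, 0.75)
  expect_lte(censored_frac, 0.85)
})

test_that("a fivefold hazard contrast is detectable by log-rank at n = 300", {
  cfg <- synthetic_config(n_samples = 300, seed = 12,
                          views = list(view_spec("v", 10, 2, 1)),
                          k_true = 2, cluster_proportions = c(0.5, 0.5),
                          baseline_hazard = c(0.0002, 0.001),
                          censoring_rate_target = 0.8)
  set.seed(12)
  labels <- sample(1:2, 300, replace = TRUE)
  sv <- simulate_survival(labels, cfg)
  expect_lt(logrank_test(sv, labels)$p, 0.001)
})

test_that("identical hazards give uniform log-rank p-values under the null", {
  cfg <- synthetic_config(n_samples = 150, seed = 1,
                          views = list(view_spec("v", 10, 2, 1)),
                          k_true = 2, cluster_proportions = c(0.5, 0.5),
                          baseline_hazard = c(0.001, 0.001),
                          censoring_rate_target = 0.5)
  set.seed(99)
  pvals <- replicate(200, {
    labels <- sample(1:2, 150, replace = TRUE)
    sv <- simulate_survival(labels, cfg)
    logrank_test(sv, labels)$p
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("endpoint flips behave as configured", {
  cfg <- synthetic_config(n_samples = 100, seed = 4, os_flip_prob = 0,
                          views = list(view_spec("v", 20, 5, 1)),
                          k_true = 2, cluster_proportions = c(0.5, 0.5),
                          baseline_hazard = c(0.0005, 0.002))
  d <- simulate_cohort(cfg)
  expect_identical(d$clinical$os_event, d$truth$os$event)
  expect_identical(d$clinical$os_time, d$truth$os$time)
})

test_that("ground truth is written as a separate sidecar, never inside inputs", {
  d <- small_cohort(n = 15)
  dir <- withr::local_tempdir()
  write_cohort(d, dir)
  files <- list.files(dir)
  expect_true("ground_truth.json" %in% files)
  expect_true("clinical.csv" %in% files)
  # pipeline input files carry no label column
  cl <- utils::read.csv(file.path(dir, "clinical.csv"))
  expect_false(any(grepl("label|truth|cluster", names(cl), ignore.case = TRUE)))
  v <- read_expression(file.path(dir, "v1.tsv"), platform = "v1")
  expect_equal(v$values, d$views$v1$values, tolerance = 0)
})
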