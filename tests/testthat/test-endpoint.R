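test_that("ANOVA F scores match hand computation and degenerate conventions", {
  # 2 vs 2 hand case: A = (0, 1), B = (2, 3) -> F = 8
  X <- matrix(c(0, 1, 2, 3), 4, 1)
  expect_equal(anova_f_scores(X, c(0, 0, 1, 1)), 8)
  # identical class means with nonzero variance: F ~ 0
  X2 <- matrix(c(0, 1, 0, 1), 4, 1)
  expect_equal(anova_f_scores(X2, c(0, 0, 1, 1)), 0)
  # zero within-class variance with separated means: Inf, ranked first
  X3 <- cbind(g1 = c(0, 0, 1, 1), g2 = rnorm(4))
  f3 <- anova_f_scores(X3, c(0, 0, 1, 1))
  expect_equal(unname(f3[1]), Inf)
  expect_equal(order(f3, decreasing = TRUE)[1], 1)
  expect_error(anova_f_scores(X3, rep(0, 4)), "two classes")
  # oracle: matches R's one-way ANOVA F on random data
  set.seed(1)
  Xr <- matrix(rnorm(60), 20, 3)
  y <- rep(0:1, 10)
  fr <- anova_f_scores(Xr, y)
  for (j in 1:3) {
    expect_equal(fr[j], unname(summary(aov(Xr[, j] ~ factor(y)))[[1]]$`F value`[1]),
                 tolerance = 1e-8)
  }
})

test_that("AUROC equals brute-force pair counting; balanced accuracy at sign threshold", {
  # spec toys
  m <- evaluate_binary(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
  expect_equal(m$auroc, 0.75)
  expect_equal(evaluate_binary(c(0, 1), c(-1, 1))$auroc, 1)
  # all-majority prediction on a 90/10 split: balanced accuracy 0.5
  y <- c(rep(0, 18), rep(1, 2))
  expect_equal(evaluate_binary(y, rep(-1, 20))$balanced_accuracy, 0.5)
  # pair-counting oracle with ties
  set.seed(7)
  for (rep in 1:10) {
    y <- rbinom(50, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, by = 0.1), 50, replace = TRUE)
    pos <- which(y == 1); neg <- which(y == 0)
    cmp <- outer(s[pos], s[neg], function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(evaluate_binary(y, s)$auroc, mean(cmp))
  }
  expect_error(evaluate_binary(rep(1, 5), rnorm(5)), "single-class")
})

test_that("balanced accuracy is prevalence-invariant at fixed sensitivity/specificity", {
  # sens = 1, spec = 0.5 under two very different prevalences
  y1 <- c(rep(1, 2), rep(0, 4)); s1 <- c(1, 1, -1, -1, 1, 1)
  y2 <- c(rep(1, 10), rep(0, 4)); s2 <- c(rep(1, 10), -1, -1, 1, 1)
  expect_equal(evaluate_binary(y1, s1)$balanced_accuracy,
               evaluate_binary(y2, s2)$balanced_accuracy)
})

test_that("tuned classifier separates separable data and is seed-deterministic", {
  set.seed(11)
  X <- matrix(rnorm(80 * 30), 80, 30)
  y <- rbinom(80, 1, 0.5)
  X[y == 1, 1:5] <- X[y == 1, 1:5] + 4
  colnames(X) <- paste0("g", 1:30)
  spec <- train_tuned_classifier(X, y, C_grid = c(0.01, 1, 100),
                                 feature_count = 10, seed = 2)
  scores <- predict(spec, X)
  expect_equal(mean((scores > 0) == (y == 1)), 1)
  spec2 <- train_tuned_classifier(X, y, C_grid = c(0.01, 1, 100),
                                  feature_count = 10, seed = 2)
  expect_identical(spec$C, spec2$C)
  expect_identical(spec$class_weight_mode, spec2$class_weight_mode)
  expect_identical(spec$selected_features, spec2$selected_features)
  # the informative genes dominate the selected set
  expect_true(all(1:5 %in% spec$selected_features))
})

test_that("the C grid reading is monotone by default with a literal alternative", {
  expect_equal(default_C_grid()[1:4], c(1e-6, 1e-5, 1e-4, 1e-3))
  expect_true(!is.unsorted(default_C_grid()))
  expect_equal(default_C_grid(literal = TRUE)[1:4], c(1e6, 1e5, 1e4, 1e3))
  expect_equal(length(default_C_grid()), 14)
})

test_that("feature selection happens inside training folds only (no leakage)", {
  set.seed(13)
  X <- matrix(rnorm(60 * 40), 60, 40)
  y <- rep(0:1, 30)
  colnames(X) <- paste0("g", 1:40)
  train_ix <- 1:40
  s1 <- train_tuned_classifier(X[train_ix, ], y[train_ix],
                               C_grid = 1, feature_count = 5, seed = 3)
  # perturbing rows outside the training set cannot change the trained model
  X2 <- X; X2[41:60, ] <- matrix(rnorm(20 * 40), 20, 40)
  s2 <- train_tuned_classifier(X2[train_ix, ], y[train_ix],
                               C_grid = 1, feature_count = 5, seed = 3)
  expect_identical(s1$selected_features, s2$selected_features)
  expect_identical(s1$C, s2$C)
})

test_that("context filters subset train and test identically", {
  d <- small_cohort(n = 50, seed = 20)
  filtered <- mvkkm:::filter_context(d, "hr")
  expect_true(all(filtered$clinical$high_risk == 1))
  expect_equal(nrow(filtered$clinical), sum(d$clinical$high_risk))
  mna <- mvkkm:::filter_context(d, "mycn-na")
  expect_true(all(mna$clinical$mycn_amplified == 0, na.rm = TRUE))
  expect_false(anyNA(mna$clinical$mycn_amplified))
  expect_error(mvkkm:::filter_context(d, "nonsense"), "unknown context")
})

test_that("same-cohort prediction on a separable signal is a sanity ceiling", {
  cfg <- synthetic_config(
    n_samples = 80, k_true = 2, cluster_proportions = c(0.5, 0.5),
    views = list(view_spec("expr", n_genes = 300, n_informative = 30,
                           effect_size = 3)),
    baseline_hazard = c(0.0002, 0.001), seed = 31)
  d <- simulate_multiview(cfg)
  cl <- toy_clinical(d$views[[1]]$samples,
                     os_event = as.integer(d$truth$labels == 2),
                     os_time = rep(1, 80),
                     high_risk = as.integer(d$truth$labels == 2))
  ds <- multiview_dataset(d$views, cl)
  rep <- cross_cohort_predict(ds, ds, endpoint = "os", context = "all",
                              C_grid = c(0.01, 1), feature_count = 100, seed = 4)
  expect_gte(rep$auroc, 0.99)
  expect_s3_class(rep, "EndpointReport")
})
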