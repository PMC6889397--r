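#' The misclassification-cost grid for the linear SVM
#'
#' The printed grid mixes large powers of ten with small values; the default
#' reading takes the leading powers as negative exponents
#' (`1e-6 ... 1e-3, 0.1, 0.5, ..., 1000`), which makes the sequence monotone
#' and matches common practice. Set `literal = TRUE` for the literal
#' positive-exponent reading.
#'
#' @param literal logical; return `1e6, 1e5, 1e4, 1e3, 0.1, ...` instead.
#' @export
default_C_grid <- function(literal = FALSE) {
  head <- if (literal) c(1e6, 1e5, 1e4, 1e3) else c(1e-6, 1e-5, 1e-4, 1e-3)
  c(head, 0.1, 0.5, 1, 2, 5, 10, 20, 50, 100, 1000)
}

#' One-way ANOVA F statistics per gene
#'
#' Between-group over within-group mean squares for each gene (column),
#' against the class labels. Genes with zero within-group variance but
#' separated class means score `Inf` and therefore rank first.
#'
#' @param X samples x genes matrix.
#' @param y class labels (two or more classes, each nonempty).
#' @return numeric vector of F statistics, one per gene.
#' @export
anova_f_scores <- function(X, y) {
  X <- as.matrix(X)
  y <- as.factor(y)
  g <- nlevels(droplevels(y))
  if (g < 2) stop("anova_f_scores: need at least two classes")
  n <- nrow(X)
  grand <- colMeans(X)
  ssb <- numeric(ncol(X))
  ssw <- numeric(ncol(X))
  for (lev in levels(droplevels(y))) {
    ix <- which(y == lev)
    mg <- colMeans(X[ix, , drop = FALSE])
    ssb <- ssb + length(ix) * (mg - grand)^2
    ssw <- ssw + colSums((X[ix, , drop = FALSE] - rep(mg, each = length(ix)))^2)
  }
  msb <- ssb / (g - 1)
  msw <- ssw / (n - g)
  f <- msb / msw
  f[msw == 0 & msb > 0] <- Inf
  f[msw == 0 & msb == 0] <- 0
  f
}

# top-k gene indices by ANOVA F (computed on training data only)
select_top_features <- function(X, y, feature_count) {
  f <- anova_f_scores(X, y)
  head(order(f, decreasing = TRUE), min(feature_count, ncol(X)))
}

# fit a linear SVM; returns a scorer giving decision values oriented so that
# larger score = class "1"
fit_linear_svm <- function(X, y, C, balanced) {
  yf <- factor(y, levels = c(0, 1))
  cw <- if (balanced) {
    tab <- table(yf)
    stats::setNames(length(y) / (2 * as.numeric(tab)), names(tab))
  } else NULL
  model <- e1071::svm(x = X, y = yf, kernel = "linear", cost = C,
                      class.weights = cw, scale = FALSE)
  # orient decision values so that larger score favors class "1": e1071's
  # decision column sign follows the label order seen at fit time
  nm <- colnames(attr(stats::predict(model, X[1, , drop = FALSE],
                                     decision.values = TRUE),
                      "decision.values"))[1]
  flip <- if (identical(nm, "1/0")) 1 else -1
  list(model = model, flip = flip)
}

svm_scores <- function(fitted, X) {
  dv <- attr(stats::predict(fitted$model, X, decision.values = TRUE),
             "decision.values")
  fitted$flip * as.numeric(dv)
}

#' AUROC and balanced accuracy of decision scores
#'
#' AUROC is the Mann-Whitney probability that a positive outscores a negative
#' (ties count 0.5); balanced accuracy is `(sensitivity + specificity) / 2` at
#' the sign threshold (score > 0 predicts the positive class).
#'
#' @param y_true binary labels (0/1), both classes present.
#' @param scores real decision values, larger = more positive.
#' @return list: `auroc`, `balanced_accuracy`.
#' @export
evaluate_binary <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (length(unique(y_true)) < 2) stop("evaluate_binary: single-class truth")
  n1 <- sum(y_true == 1L)
  n0 <- sum(y_true == 0L)
  r <- rank(scores)  # midranks handle ties as 0.5
  auroc <- (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(scores > 0)
  sens <- sum(pred == 1L & y_true == 1L) / n1
  spec <- sum(pred == 0L & y_true == 0L) / n0
  list(auroc = auroc, balanced_accuracy = (sens + spec) / 2)
}

#' Train a nested-CV-tuned linear classifier
#'
#' The supervised protocol: inside each inner fold, the top `feature_count`
#' genes are selected by ANOVA F on that fold's training part only (no
#' leakage); a linear SVM is fitted for every (C, class-weight mode)
#' combination and scored on the held-out part. The setting with the best mean
#' inner accuracy wins (ties: smaller C, then uniform weights) and the final
#' model is refitted on all data with features reselected on all data.
#' Balanced mode multiplies each class's C inversely to its frequency.
#'
#' @param X samples x genes training matrix.
#' @param y binary labels (0/1).
#' @param C_grid candidate costs; defaults to [default_C_grid()].
#' @param feature_count number of genes kept by the ANOVA-F filter.
#' @param inner_folds inner cross-validation folds.
#' @param weight_modes candidate class-weight modes.
#' @param seed fold-assignment seed.
#' @return An object of class `ClassifierSpec`: `C`, `class_weight_mode`,
#'   `selected_features` (indices into the training gene set),
#'   `feature_names`, `inner_accuracy`, plus the fitted model.
#' @export
train_tuned_classifier <- function(X, y, C_grid = default_C_grid(),
                                   feature_count = 1000, inner_folds = 5,
                                   weight_modes = c("uniform", "balanced"),
                                   seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(C_grid) == 0) stop("train_tuned_classifier: empty C grid")
  if (length(unique(y)) < 2) stop("train_tuned_classifier: single-class labels")
  n <- nrow(X)
  if (n < inner_folds) stop("train_tuned_classifier: fewer samples than folds")
  rng <- make_rng(seed)
  assignment <- stratified_folds(y, inner_folds, rng)

  grid <- expand.grid(C = sort(C_grid), mode = weight_modes,
                      stringsAsFactors = FALSE)
  acc <- matrix(NA_real_, nrow(grid), inner_folds)
  for (f in seq_len(inner_folds)) {
    test <- which(assignment == f)
    train <- setdiff(seq_len(n), test)
    if (length(unique(y[train])) < 2) next
    feats <- select_top_features(X[train, , drop = FALSE], y[train], feature_count)
    Xtr <- X[train, feats, drop = FALSE]
    Xte <- X[test, feats, drop = FALSE]
    for (gidx in seq_len(nrow(grid))) {
      fitted <- fit_linear_svm(Xtr, y[train], grid$C[gidx],
                               grid$mode[gidx] == "balanced")
      pred <- as.integer(svm_scores(fitted, Xte) > 0)
      acc[gidx, f] <- mean(pred == y[test])
    }
  }
  mean_acc <- rowMeans(acc, na.rm = TRUE)
  # ties: smaller C first, uniform before balanced (grid is ordered that way)
  best <- which.max(mean_acc)
  feats <- select_top_features(X, y, feature_count)
  fitted <- fit_linear_svm(X[, feats, drop = FALSE], y, grid$C[best],
                           grid$mode[best] == "balanced")
  structure(list(C = grid$C[best], class_weight_mode = grid$mode[best],
                 selected_features = feats,
                 feature_names = colnames(X)[feats],
                 inner_accuracy = mean_acc[best],
                 fitted = fitted),
            class = "ClassifierSpec")
}

#' @export
print.ClassifierSpec <- function(x, ...) {
  cat(sprintf("ClassifierSpec: linear SVM, C = %g, weights = %s, %d features, inner accuracy = %.3f\n",
              x$C, x$class_weight_mode, length(x$selected_features),
              x$inner_accuracy))
  invisible(x)
}

#' Decision scores of a tuned classifier on new samples
#' @param object a [train_tuned_classifier()] result.
#' @param newdata samples x genes matrix over the same gene set the classifier
#'   was trained on.
#' @param ... unused.
#' @export
predict.ClassifierSpec <- function(object, newdata, ...) {
  svm_scores(object$fitted,
             as.matrix(newdata)[, object$selected_features, drop = FALSE])
}

# context filter over a MultiViewDataset: all / hr / mycn-na
filter_context <- function(data, context) {
  cl <- data$clinical
  keep <- switch(context,
                 all = rep(TRUE, length(cl$sample)),
                 hr = cl$high_risk == 1L,
                 `mycn-na` = !is.na(cl$mycn_amplified) & cl$mycn_amplified == 0L,
                 stop("filter_context: unknown context '", context, "'"))
  if (!any(keep)) stop("filter_context: no samples left after '", context, "' filter")
  views <- lapply(data$views, function(v) {
    expression_view(v$values[keep, , drop = FALSE], name = v$name,
                    platform = v$platform)
  })
  clinical <- cl[keep, ]
  class(clinical) <- class(cl)
  multiview_dataset(views, clinical)
}

#' Cross-cohort endpoint prediction
#'
#' Harmonizes genes between the two cohorts, applies the same context filter
#' (all patients, high-risk only, or MYCN-non-amplified only) to both, tunes a
#' classifier on the training cohort's chosen expression view, and scores the
#' test cohort by AUROC and balanced accuracy.
#'
#' @param train,test [multiview_dataset()] objects with clinical tables.
#' @param endpoint `"os"` or `"efs"`.
#' @param context `"all"`, `"hr"`, or `"mycn-na"`.
#' @param view view name used for the model; defaults to the first common view.
#' @param ... passed to [train_tuned_classifier()].
#' @return list of class `EndpointReport`: `endpoint`, `context`, `view`,
#'   `auroc`, `balanced_accuracy`, `chosen_C`, `chosen_weight_mode`.
#' @export
cross_cohort_predict <- function(train, test, endpoint = c("os", "efs"),
                                 context = c("all", "hr", "mycn-na"),
                                 view = NULL, ...) {
  endpoint <- match.arg(endpoint)
  context <- match.arg(context)
  h <- harmonize_genes(train, test)
  tr <- filter_context(h$a, context)
  te <- filter_context(h$b, context)
  if (is.null(view)) view <- intersect(names(tr$views), names(te$views))[1L]
  label_col <- paste0(endpoint, "_event")
  y_tr <- tr$clinical[[label_col]]
  y_te <- te$clinical[[label_col]]
  if (length(unique(y_tr)) < 2 || length(unique(y_te)) < 2) {
    stop("cross_cohort_predict: endpoint labels single-class after filtering")
  }
  spec <- train_tuned_classifier(tr$views[[view]]$values, y_tr, ...)
  scores <- predict(spec, te$views[[view]]$values)
  metrics <- evaluate_binary(y_te, scores)
  structure(list(endpoint = toupper(endpoint), context = context, view = view,
                 auroc = metrics$auroc,
                 balanced_accuracy = metrics$balanced_accuracy,
                 chosen_C = spec$C, chosen_weight_mode = spec$class_weight_mode,
                 classifier = spec),
            class = "EndpointReport")
}

#' @export
print.EndpointReport <- function(x, ...) {
  cat(sprintf("EndpointReport %s [%s], view %s: AUROC = %.3f, balanced accuracy = %.3f (C = %g, %s)\n",
              x$endpoint, x$context, x$view, x$auroc, x$balanced_accuracy,
              x$chosen_C, x$chosen_weight_mode))
  invisible(x)
}

#' Write endpoint reports to CSV
#' @param reports list of `EndpointReport` objects.
#' @param path output CSV path.
#' @export
write_endpoint_reports <- function(reports, path) {
  if (inherits(reports, "EndpointReport")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(endpoint = r$endpoint, context = r$context, view = r$view,
               auroc = r$auroc, balanced_accuracy = r$balanced_accuracy,
               C = r$chosen_C, weight_mode = r$chosen_weight_mode)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
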