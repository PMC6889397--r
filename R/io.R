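#' Construct an expression view
#'
#' An expression view is one molecular data type (e.g. RNA-seq MAV, RNA-seq RPM,
#' microarray, aCGH) measured on a common sample set, stored samples x genes on
#' the log2 scale (log-ratio scale for aCGH).
#'
#' @param values numeric matrix, samples in rows, genes in columns.
#' @param name view label, e.g. `"rnaseq-mav"`.
#' @param platform platform label: one of `"rnaseq-mav"`, `"rnaseq-rpm"`,
#'   `"microarray"`, `"acgh"`, or any other label.
#' @param genes,samples identifier vectors; default to the dimnames of `values`.
#' @return An object of class `ExpressionView`.
#' @export
expression_view <- function(values, name, platform = name,
                            genes = colnames(values),
                            samples = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(genes) || is.null(samples)) {
    stop("expression_view: gene and sample identifiers are required")
  }
  genes <- as.character(genes)
  samples <- as.character(samples)
  if (anyDuplicated(genes)) stop("expression_view: duplicate gene identifiers")
  if (anyDuplicated(samples)) stop("expression_view: duplicate sample identifiers")
  if (nrow(values) != length(samples) || ncol(values) != length(genes)) {
    stop("expression_view: matrix dimensions do not match identifier lists")
  }
  if (!all(is.finite(values))) stop("expression_view: non-finite values")
  storage.mode(values) <- "double"
  dimnames(values) <- list(samples, genes)
  structure(
    list(name = name, platform = platform, genes = genes,
         samples = samples, values = values),
    class = "ExpressionView"
  )
}

#' @export
print.ExpressionView <- function(x, ...) {
  cat(sprintf("ExpressionView '%s' (%s): %d samples x %d genes\n",
              x$name, x$platform, length(x$samples), length(x$genes)))
  invisible(x)
}

#' Read an expression matrix from a TSV file
#'
#' Tab-separated text, first column gene identifiers (or sample identifiers when
#' `genes_in_rows = FALSE`), header row with the other identifier set. Internal
#' orientation is always samples x genes; file orientation is declared
#' explicitly, never guessed. Duplicate gene rows are collapsed by their
#' arithmetic mean.
#'
#' @param path file path.
#' @param platform platform label stored on the view.
#' @param name view label; defaults to the platform.
#' @param genes_in_rows logical; `TRUE` (default) means the file is
#'   genes x samples and is transposed on read.
#' @return An [expression_view()].
#' @export
read_expression <- function(path, platform, name = platform, genes_in_rows = TRUE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", row.names = NULL)
  if (ncol(raw) < 2 || nrow(raw) < 1) {
    stop(sprintf("read_expression: empty or malformed matrix in '%s'", path))
  }
  row_ids <- raw[[1L]]
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "read_expression: non-numeric cell at row '%s', column '%s' in '%s'",
      row_ids[bad[1, 1]], colnames(mat)[bad[1, 2]], path))
  }
  dimnames(num) <- list(row_ids, colnames(mat))
  if (genes_in_rows) num <- t(num)
  # now samples x genes; collapse duplicated gene columns by mean
  gid <- colnames(num)
  if (anyDuplicated(gid)) {
    num <- vapply(split(seq_along(gid), gid)[unique(gid)],
                  function(ix) rowMeans(num[, ix, drop = FALSE]),
                  numeric(nrow(num)))
  }
  expression_view(num, name = name, platform = platform)
}

#' Write an expression view to a TSV file
#'
#' Inverse of [read_expression()]: values are written genes x samples (or
#' samples x genes with `genes_in_rows = FALSE`) with full precision, so a
#' write/read round trip reproduces the view exactly.
#'
#' @inheritParams read_expression
#' @param view an [expression_view()].
#' @export
write_expression <- function(view, path, genes_in_rows = TRUE) {
  stopifnot(inherits(view, "ExpressionView"))
  m <- if (genes_in_rows) t(view$values) else view$values
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1L] <- if (genes_in_rows) "gene" else "sample"
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a clinical table
#'
#' @param df data.frame with columns `sample`, `os_event`, `os_time`,
#'   `efs_event`, `efs_time`, `high_risk`, `mycn_amplified`, `age`, `stage`.
#'   `mycn_amplified` may contain `NA` (the cohorts have missing MYCN status).
#' @return data.frame of class `ClinicalTable`.
#' @export
clinical_table <- function(df) {
  need <- c("sample", "os_event", "os_time", "efs_event", "efs_time",
            "high_risk", "mycn_amplified", "age", "stage")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("clinical_table: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, need]
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample)) stop("clinical_table: duplicate sample identifiers")
  for (col in c("os_time", "efs_time", "age")) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(df[[col]] < 0, na.rm = TRUE)) {
      stop(sprintf("clinical_table: negative values in '%s'", col))
    }
  }
  for (col in c("os_event", "efs_event", "high_risk", "mycn_amplified")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (any(!v %in% c(0L, 1L) & !is.na(v))) {
      stop(sprintf("clinical_table: '%s' outside {0,1}", col))
    }
    if (col != "mycn_amplified" && anyNA(v)) {
      stop(sprintf("clinical_table: missing values in '%s'", col))
    }
    df[[col]] <- v
  }
  df$stage <- as.integer(df$stage)
  class(df) <- c("ClinicalTable", "data.frame")
  df
}

#' Read a clinical table from CSV
#'
#' Blank or NA cells in the `mycn_amplified` column are kept as missing, never
#' recoded to 0.
#'
#' @param path CSV file path with named columns for all clinical fields.
#' @return A [clinical_table()].
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        na.strings = c("NA", ""), stringsAsFactors = FALSE)
  clinical_table(df)
}

#' Write a clinical table to CSV
#' @param clinical a [clinical_table()].
#' @param path output CSV path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(as.data.frame(clinical), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Bundle expression views and clinical data into one cohort
#'
#' The unit of analysis: all views and the clinical table must cover an
#' identical, identically ordered sample list.
#'
#' @param views list of [expression_view()] objects (named by view where the
#'   list is unnamed, view names are used).
#' @param clinical optional [clinical_table()] over the same samples.
#' @param truth optional ground-truth sidecar (synthetic cohorts only); kept
#'   separate from pipeline inputs.
#' @return An object of class `MultiViewDataset`.
#' @export
multiview_dataset <- function(views, clinical = NULL, truth = NULL) {
  if (length(views) == 0) stop("multiview_dataset: at least one view required")
  if (inherits(views, "ExpressionView")) views <- list(views)
  if (is.null(names(views)) || any(names(views) == "")) {
    names(views) <- vapply(views, function(v) v$name, character(1))
  }
  ref <- views[[1L]]$samples
  for (v in views) {
    if (!identical(v$samples, ref)) {
      stop("multiview_dataset: views do not share an identical sample list")
    }
  }
  if (!is.null(clinical) && !identical(clinical$sample, ref)) {
    stop("multiview_dataset: clinical samples differ from view samples")
  }
  structure(list(views = views, clinical = clinical, truth = truth),
            class = "MultiViewDataset")
}

#' @export
print.MultiViewDataset <- function(x, ...) {
  cat(sprintf("MultiViewDataset: %d samples, %d view(s)\n",
              length(x$views[[1L]]$samples), length(x$views)))
  for (v in x$views) {
    cat(sprintf("  - %s (%s): %d genes\n", v$name, v$platform, length(v$genes)))
  }
  cat(if (is.null(x$clinical)) "  no clinical table\n" else "  clinical table attached\n")
  invisible(x)
}

#' Restrict two cohorts to their common genes
#'
#' Every view in both datasets is cut down to the intersection of all gene sets
#' and reordered into a single canonical (sorted) gene order, so cross-cohort
#' models see identical feature spaces. Matching is by exact identifier string.
#'
#' @param a,b [multiview_dataset()] objects.
#' @return list with elements `a` and `b`, the harmonized datasets.
#' @export
harmonize_genes <- function(a, b) {
  stopifnot(inherits(a, "MultiViewDataset"), inherits(b, "MultiViewDataset"))
  gene_sets <- lapply(c(a$views, b$views), function(v) v$genes)
  common <- Reduce(intersect, gene_sets)
  if (length(common) == 0) {
    stop("harmonize_genes: no genes shared between the two cohorts")
  }
  common <- sort(common)
  cut <- function(ds) {
    ds$views <- lapply(ds$views, function(v) {
      expression_view(v$values[, common, drop = FALSE],
                      name = v$name, platform = v$platform)
    })
    ds
  }
  list(a = cut(a), b = cut(b))
}

#' Reverse aCGH intensity signs for mislabeled samples
#'
#' Applies the tumor/normal label correction used for the aCGH data: rows of
#' the listed samples are multiplied by -1. Applying the correction twice
#' restores the original matrix.
#'
#' @param view an [expression_view()] with platform `"acgh"`.
#' @param sample_ids character vector of sample identifiers to flip.
#' @return The corrected `ExpressionView`.
#' @export
flip_acgh_signs <- function(view, sample_ids) {
  stopifnot(inherits(view, "ExpressionView"))
  if (!identical(view$platform, "acgh")) {
    stop("flip_acgh_signs: view platform must be 'acgh'")
  }
  sample_ids <- as.character(sample_ids)
  missing_ids <- setdiff(sample_ids, view$samples)
  if (length(missing_ids)) {
    stop("flip_acgh_signs: unknown sample ids: ", paste(missing_ids, collapse = ", "))
  }
  ix <- match(sample_ids, view$samples)
  view$values[ix, ] <- -view$values[ix, , drop = FALSE]
  view
}

#' Read a plain-text list of sample identifiers
#'
#' One identifier per line; blank lines ignored. Used for the aCGH sign-flip
#' list.
#'
#' @param path file path.
#' @return character vector.
#' @export
read_sample_list <- function(path) {
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids[nzchar(ids)]
}
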