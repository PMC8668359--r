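#' Construct a feature matrix with aligned labels
#'
#' The central container of the toolkit: a samples-by-features numeric matrix
#' together with a per-row class label and per-column provenance identifiers.
#' Every stage of the pipeline (extraction, fusion, selection, evaluation)
#' consumes and produces this class.
#'
#' @param values Numeric matrix, one row per sample.
#' @param labels Factor (or coercible) of length `nrow(values)` giving the
#'   class of each row.
#' @param column_ids Character vector of unique column identifiers carrying
#'   provenance (e.g. `"resnet50_0007"`). Defaults to `"f0001"...`.
#' @param source_tag One of `"resnet50"`, `"resnet101"`, `"mock"`, `"fused"`,
#'   `"selected"`, or `"synthetic"`; records which stage produced the matrix.
#' @return An object of class `feature_matrix` with fields `values`, `labels`,
#'   `column_ids`, `source_tag`.
#' @examples
#' fm <- feature_matrix(matrix(rnorm(20), 5), labels = rep(c("a", "b"), c(2, 3)))
#' dim(fm$values)
#' @export
feature_matrix <- function(values, labels,
                           column_ids = NULL,
                           source_tag = "synthetic") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  labels <- as.factor(labels)
  if (nrow(values) != length(labels)) {
    stop(sprintf("row count (%d) != label count (%d)", nrow(values), length(labels)),
         call. = FALSE)
  }
  if (is.null(column_ids)) {
    column_ids <- sprintf("f%04d", seq_len(ncol(values)))
  }
  column_ids <- as.character(column_ids)
  if (length(column_ids) != ncol(values)) {
    stop("column_ids length must equal the number of columns", call. = FALSE)
  }
  if (anyDuplicated(column_ids)) stop("column_ids must be unique", call. = FALSE)
  source_tag <- match.arg(source_tag,
                          c("synthetic", "resnet50", "resnet101", "mock",
                            "fused", "selected"))
  colnames(values) <- column_ids
  structure(list(values = values, labels = labels,
                 column_ids = column_ids, source_tag = source_tag),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features [%s]\n",
              nrow(x$values), ncol(x$values), x$source_tag))
  tab <- table(x$labels)
  cat("classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Subset the columns of a feature matrix
#'
#' @param fm A [feature_matrix()].
#' @param idx Integer column indices to keep (order preserved).
#' @param source_tag Optional new source tag; defaults to the input's.
#' @return A `feature_matrix` restricted to the requested columns.
#' @export
fm_subset_columns <- function(fm, idx, source_tag = fm$source_tag) {
  stopifnot(inherits(fm, "feature_matrix"))
  idx <- as.integer(idx)
  if (length(idx) && (min(idx) < 1L || max(idx) > ncol(fm$values))) {
    stop("column index out of range", call. = FALSE)
  }
  feature_matrix(fm$values[, idx, drop = FALSE], fm$labels,
                 column_ids = fm$column_ids[idx], source_tag = source_tag)
}

#' Write a feature matrix to CSV
#'
#' Persists as plain CSV with a header row of column identifiers and a final
#' `label` column, the interchange format used by every pipeline stage.
#'
#' @param fm A [feature_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(fm$values)
  names(df) <- fm$column_ids
  df$label <- as.character(fm$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' @param path CSV file written by [write_feature_csv()] (numeric feature
#'   columns plus a final `label` column).
#' @param source_tag Source tag to attach; defaults to `"synthetic"`.
#' @return A [feature_matrix()].
#' @export
read_feature_csv <- function(path, source_tag = "synthetic") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) stop("no `label` column in ", path, call. = FALSE)
  lab <- df$label
  df$label <- NULL
  feature_matrix(as.matrix(df), lab, column_ids = names(df),
                 source_tag = source_tag)
}
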