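#' Serially concatenate two feature matrices
#'
#' Column-wise (serial) fusion: an n-dimensional and an m-dimensional feature
#' vector per sample combine into one (n+m)-dimensional vector. Rows must
#' align sample-for-sample: equal counts and element-wise identical labels.
#'
#' @param f1,f2 [feature_matrix()] objects over the same samples.
#' @return A `feature_matrix` of width `ncol(f1) + ncol(f2)` with `f1`'s
#'   columns first; column ids keep their source provenance, `source_tag`
#'   becomes `"fused"`.
#' @export
serial_concat <- function(f1, f2) {
  stopifnot(inherits(f1, "feature_matrix"), inherits(f2, "feature_matrix"))
  if (nrow(f1$values) != nrow(f2$values)) {
    stop(sprintf("row counts differ: %d vs %d",
                 nrow(f1$values), nrow(f2$values)), call. = FALSE)
  }
  mismatch <- which(as.character(f1$labels) != as.character(f2$labels))
  if (length(mismatch)) {
    stop(sprintf("label mismatch at row %d ('%s' vs '%s')",
                 mismatch[1], f1$labels[mismatch[1]], f2$labels[mismatch[1]]),
         call. = FALSE)
  }
  if (ncol(f2$values) == 0L || ncol(f1$values) == 0L) {
    stop("cannot fuse a zero-width feature matrix", call. = FALSE)
  }
  # "a."/"b." prefixes keep ids unique even when both inputs come from the
  # same backbone family; the original provenance stays in the suffix
  ids <- c(paste0("a.", f1$column_ids), paste0("b.", f2$column_ids))
  feature_matrix(cbind(f1$values, f2$values), f1$labels,
                 column_ids = ids, source_tag = "fused")
}

# Per-column summary used by the SEM and skewness thresholds: the mean of
# each feature over samples.
column_means <- function(fm) colMeans(fm$values)

#' Threshold fused features by the standard error of the mean
#'
#' Computes the per-column mean \eqn{c_j} over samples, the sample standard
#' deviation \eqn{s} of the vector \eqn{(c_1, \dots, c_d)} (with the
#' \eqn{n-1} denominator), and the standard error of the mean
#' \eqn{SEM = s/\sqrt{d}}. A column is kept iff \eqn{c_j \ge SEM} (ties
#' kept). With deep ReLU-derived features all column means are nonnegative;
#' a signed column mean below the SEM is discarded like any other.
#'
#' @param fm A non-empty [feature_matrix()] (typically [serial_concat()]
#'   output).
#' @return An object of class `fusion_result`: `fused` (kept columns as a
#'   `feature_matrix`), `kept_idx`, `discarded_idx`, `sem`, `s`, and
#'   `column_summary` (the per-column means).
#' @examples
#' fm <- feature_matrix(matrix(rep(1:5, each = 4), 4), rep(c("a", "b"), 2))
#' sem_threshold(fm)$sem  # sd(1:5)/sqrt(5)
#' @export
sem_threshold <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (ncol(fm$values) == 0L || nrow(fm$values) == 0L) {
    stop("empty feature matrix", call. = FALSE)
  }
  cm <- column_means(fm)
  d <- length(cm)
  s <- if (d > 1L) stats::sd(cm) else 0
  sem <- s / sqrt(d)
  kept <- unname(which(cm >= sem))
  structure(list(
    fused = fm_subset_columns(fm, kept, source_tag = "fused"),
    kept_idx = kept,
    discarded_idx = setdiff(seq_len(d), kept),
    sem = sem, s = s, column_summary = cm),
    class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result> kept %d / %d columns (s = %.4g, SEM = %.4g)\n",
              length(x$kept_idx), length(x$kept_idx) + length(x$discarded_idx),
              x$s, x$sem))
  invisible(x)
}

#' Modified serial fusion: concatenate then SEM-threshold
#'
#' The two sequential steps of the fusion stage: [serial_concat()] followed
#' by [sem_threshold()]. Deterministic — no randomness anywhere.
#'
#' @inheritParams serial_concat
#' @return A `fusion_result` (see [sem_threshold()]).
#' @export
fuse_features <- function(f1, f2) {
  sem_threshold(serial_concat(f1, f2))
}
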