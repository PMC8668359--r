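# Seeded stratified train/test indices: within each class, a fraction
# `train_fraction` (rounded) goes to train, the rest to test.
stratified_indices <- function(labels, train_fraction, seed) {
  labels <- as.factor(labels)
  train <- integer(0)
  with_seed(seed, {
    for (cls in levels(labels)) {
      idx <- which(labels == cls)
      n_tr <- round(length(idx) * train_fraction)
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      train <- c(train, sort(sample(idx, n_tr)))
    }
  })
  list(train = sort(train), test = setdiff(seq_along(labels), train))
}

fm_subset_rows <- function(fm, idx) {
  feature_matrix(fm$values[idx, , drop = FALSE], droplevels(fm$labels[idx]),
                 column_ids = fm$column_ids, source_tag = fm$source_tag)
}

#' Stratified holdout split
#'
#' Partitions a feature matrix into train and test parts, stratified by
#' class so per-class proportions are preserved within rounding. The
#' partition is exact: no overlap and every sample assigned.
#'
#' @param fm A [feature_matrix()] with at least two samples per class.
#' @param ratio Training fraction, strictly between 0 and 1 (default 0.7,
#'   the conventional 70:30 protocol).
#' @param seed Integer seed.
#' @return List with `train` and `test` [feature_matrix()]s and the index
#'   vectors `train_idx`, `test_idx`.
#' @export
split_holdout <- function(fm, ratio = 0.7, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  ratio <- assert_fraction(ratio, "ratio", 0, 1, lo_open = TRUE,
                           hi_open = TRUE)
  counts <- table(droplevels(fm$labels))
  if (any(counts < 2L)) {
    stop("every class needs >= 2 samples to split; offending class: ",
         names(counts)[which(counts < 2L)[1]], call. = FALSE)
  }
  sp <- stratified_indices(fm$labels, ratio, seed)
  list(train = fm_subset_rows(fm, sp$train),
       test = fm_subset_rows(fm, sp$test),
       train_idx = sp$train, test_idx = sp$test)
}

# Seeded stratified k-fold assignment; returns an integer fold id per sample.
stratified_folds <- function(labels, k, seed) {
  labels <- as.factor(labels)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in levels(labels)) {
      idx <- which(labels == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

# Macro one-vs-rest AUC from a score matrix via the Mann-Whitney statistic.
macro_auc <- function(labels, scores) {
  labels <- as.factor(labels)
  aucs <- vapply(levels(labels), function(cls) {
    pos <- labels == cls
    if (!any(pos) || all(pos)) return(NA_real_)
    r <- rank(scores[, cls])
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Metrics from a confusion matrix
#'
#' Macro-averaged metric suite in percent: per-class recall and precision
#' averaged across classes, false-negative rate as `100 - recall`, overall
#' accuracy as the trace over the total, and F1 as the harmonic mean of the
#' macro precision and recall. AUC is the macro one-vs-rest area computed
#' from decision scores when supplied; otherwise it falls back to the
#' confusion-derived per-class balanced accuracy, mean of sensitivity and
#' specificity.
#'
#' @param confusion Square nonnegative integer matrix, true classes in rows,
#'   predictions in columns.
#' @param labels,scores Optional true labels and per-class score matrix for
#'   the score-based AUC.
#' @return List with `recall`, `precision`, `fnr`, `auc`, `accuracy`, `f1`
#'   (percentages except `auc` in `[0, 1]`).
#' @examples
#' compute_metrics(matrix(c(8, 4, 2, 6), 2))  # accuracy 70
#' @export
compute_metrics <- function(confusion, labels = NULL, scores = NULL) {
  confusion <- as.matrix(confusion)
  if (!nrow(confusion) || nrow(confusion) != ncol(confusion)) {
    stop("confusion matrix must be square and non-empty", call. = FALSE)
  }
  if (any(confusion < 0)) stop("negative confusion counts", call. = FALSE)
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(confusion)
  rec_k <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion), NA)
  prec_k <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), 0)
  recall <- 100 * mean(rec_k, na.rm = TRUE)
  precision <- 100 * mean(prec_k)
  auc <- if (!is.null(scores) && !is.null(labels)) {
    macro_auc(labels, scores)
  } else {
    # confusion-derived fallback: mean per-class balanced accuracy
    spec_k <- vapply(seq_len(nrow(confusion)), function(k) {
      tn <- total - sum(confusion[k, ]) - sum(confusion[, k]) + confusion[k, k]
      fp <- sum(confusion[, k]) - confusion[k, k]
      if (tn + fp > 0) tn / (tn + fp) else NA_real_
    }, numeric(1))
    mean((rec_k + spec_k) / 2, na.rm = TRUE)
  }
  list(recall = recall, precision = precision, fnr = 100 - recall,
       auc = auc, accuracy = 100 * sum(tp) / total,
       f1 = if (precision + recall > 0) {
         2 * precision * recall / (precision + recall)
       } else 0)
}

confusion_from <- function(truth, pred, lev) {
  table(factor(truth, levels = lev), factor(pred, levels = lev))
}

#' Cross-validated evaluation of one classifier
#'
#' Stratified k-fold cross-validation: the confusion matrix is accumulated
#' over the k test folds (every sample predicted exactly once) and the
#' metric suite is computed from the pooled matrix and pooled scores. If
#' the smallest class has fewer than `k` members the fold count is reduced
#' with a warning.
#'
#' @param fm A [feature_matrix()].
#' @param cfg A [classifier_config()].
#' @param k Number of folds (default 10).
#' @param seed Fold-assignment seed.
#' @return List: `name`, `confusion`, `metrics` (see [compute_metrics()]),
#'   `time_sec`, `k`.
#' @export
cross_validate <- function(fm, cfg, k = 10L, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(cfg, "classifier_config"))
  k <- assert_count(k, "k", min = 2L)
  labels <- droplevels(fm$labels)
  min_class <- min(table(labels))
  if (min_class < k) {
    warning(sprintf("smallest class has %d samples; reducing folds %d -> %d",
                    min_class, k, max(2L, min_class)), call. = FALSE)
    k <- max(2L, min_class)
  }
  folds <- stratified_folds(labels, k, seed)
  lev <- levels(labels)
  pred <- factor(rep(lev[1], length(labels)), levels = lev)
  scores <- matrix(NA_real_, length(labels), length(lev),
                   dimnames = list(NULL, lev))
  t0 <- proc.time()[["elapsed"]]
  for (f in seq_len(k)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    out <- fit_predict(cfg, fm$values[tr, , drop = FALSE], labels[tr],
                       fm$values[te, , drop = FALSE])
    pred[te] <- out$pred
    if (!is.null(out$scores)) scores[te, colnames(out$scores)] <- out$scores
  }
  elapsed <- proc.time()[["elapsed"]] - t0
  conf <- confusion_from(labels, pred, lev)
  metrics <- compute_metrics(unclass(conf), labels = labels,
                             scores = if (!anyNA(scores)) scores)
  list(name = cfg$name, confusion = conf, metrics = metrics,
       time_sec = elapsed, k = k)
}

holdout_validate <- function(fm, cfg, ratio = 0.7, seed = 1L) {
  sp <- split_holdout(fm, ratio, seed)
  lev <- levels(droplevels(fm$labels))
  t0 <- proc.time()[["elapsed"]]
  out <- fit_predict(cfg, sp$train$values, sp$train$labels, sp$test$values)
  elapsed <- proc.time()[["elapsed"]] - t0
  conf <- confusion_from(as.character(sp$test$labels), as.character(out$pred),
                         lev)
  metrics <- compute_metrics(unclass(conf), labels = sp$test$labels,
                             scores = out$scores)
  list(name = cfg$name, confusion = conf, metrics = metrics,
       time_sec = elapsed, k = NA_integer_)
}

#' Run the classifier zoo
#'
#' Evaluates every configured classifier under one protocol — stratified
#' 10-fold cross-validation or a stratified 70:30 holdout — and assembles
#' the per-classifier metric table (recall, precision, FNR, AUC, accuracy,
#' wall time, F1) plus confusion matrices. The best row by accuracy is
#' flagged.
#'
#' @param fm A [feature_matrix()].
#' @param zoo List of [classifier_config()]s (default: the full
#'   [default_zoo()]).
#' @param protocol `"cv"` (default) or `"holdout"`.
#' @param k Folds for `"cv"`.
#' @param ratio Training fraction for `"holdout"`.
#' @param seed Seed for fold/split assignment.
#' @return An object of class `evaluation_report`: `table` (data frame, one
#'   row per classifier), `confusions` (named list), `protocol`.
#' @export
run_zoo <- function(fm, zoo = default_zoo(seed), protocol = c("cv", "holdout"),
                    k = 10L, ratio = 0.7, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  protocol <- match.arg(protocol)
  if (!length(zoo)) stop("empty classifier zoo", call. = FALSE)
  names_seen <- vapply(zoo, `[[`, character(1), "name")
  if (anyDuplicated(names_seen)) stop("duplicate classifier in zoo",
                                      call. = FALSE)
  rows <- lapply(zoo, function(cfg) {
    if (protocol == "cv") cross_validate(fm, cfg, k = k, seed = seed)
    else holdout_validate(fm, cfg, ratio = ratio, seed = seed)
  })
  tab <- do.call(rbind, lapply(rows, function(r) {
    data.frame(classifier = r$name,
               recall = r$metrics$recall, precision = r$metrics$precision,
               fnr = r$metrics$fnr, auc = r$metrics$auc,
               accuracy = r$metrics$accuracy, time_sec = r$time_sec,
               f1 = r$metrics$f1)
  }))
  tab$best <- seq_len(nrow(tab)) == which.max(tab$accuracy)
  confusions <- stats::setNames(lapply(rows, `[[`, "confusion"),
                                tab$classifier)
  structure(list(table = tab, confusions = confusions, protocol = protocol,
                 seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 2, ...) {
  cat(sprintf("<evaluation_report> protocol: %s\n", x$protocol))
  tab <- x$table
  num <- c("recall", "precision", "fnr", "accuracy", "f1")
  tab[num] <- lapply(tab[num], round, digits)
  tab$auc <- round(tab$auc, 3)
  tab$time_sec <- round(tab$time_sec, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as CSV
#'
#' Mirrors the conventional table column order: Recall, Precision, FNR,
#' AUC, Accuracy, Time, F1.
#'
#' @param report An [run_zoo()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  tab <- report$table[, c("classifier", "recall", "precision", "fnr", "auc",
                          "accuracy", "time_sec", "f1")]
  names(tab) <- c("Classifier", "Recall", "Precision", "FNR", "AUC",
                  "Accuracy", "Time", "F1")
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
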