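#' Pearson's second skewness coefficient
#'
#' The median-based skewness statistic \eqn{3(\bar{x} - \mathrm{median})/s},
#' with \eqn{s} the sample standard deviation (\eqn{n-1} denominator).
#'
#' @param values Numeric vector of length >= 2 with positive SD.
#' @return The skewness coefficient.
#' @examples
#' pearson_skewness(c(1, 2, 3, 4, 10))  # right-skewed: positive
#' @export
pearson_skewness <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("degenerate distribution: standard deviation is zero", call. = FALSE)
  }
  3 * (mean(values) - stats::median(values)) / s
}

#' Skewness-threshold candidate features
#'
#' Computes the skewness of the per-column mean vector and marks column `j`
#' a candidate iff its mean is at or above that skewness value. If all
#' column means are equal the statistic is undefined; every column is kept
#' and a warning is emitted.
#'
#' @param fm A non-empty [feature_matrix()].
#' @return A list with `candidates` (integer column indices), `skew` (the
#'   statistic), and `column_summary` (the per-column means).
#' @export
skew_threshold <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (ncol(fm$values) == 0L || nrow(fm$values) == 0L) {
    stop("empty feature matrix", call. = FALSE)
  }
  cm <- column_means(fm)
  if (length(cm) < 2L || stats::sd(cm) == 0) {
    warning("degenerate column means: selecting all columns", call. = FALSE)
    return(list(candidates = seq_along(cm), skew = 0, column_summary = cm))
  }
  skew <- pearson_skewness(cm)
  list(candidates = unname(which(cm >= skew)), skew = skew, column_summary = cm)
}

#' Configuration for skewness-controlled SVR feature selection
#'
#' @param target_accuracy Fitness the candidate set must reach to stop
#'   (fraction, default 0.90).
#' @param max_iterations Maximum relaxation iterations (default 5).
#' @param C SVR penalty constant (> 0).
#' @param epsilon Width of the epsilon-insensitive tube (>= 0).
#' @param gamma RBF kernel coefficient \eqn{1/(2\rho^2)}; `NULL` (default)
#'   sets \eqn{\rho} by the median pairwise distance heuristic on the
#'   training split.
#' @param relaxation Multiplicative factor (in (0, 1)) applied to the
#'   skewness threshold after each failed iteration, admitting more columns.
#' @param train_fraction Fraction of samples in the internal stratified
#'   fitness split (default 0.7).
#' @param seed Seed for the fitness split.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(target_accuracy = 0.90, max_iterations = 5L,
                             C = 1, epsilon = 0.1, gamma = NULL,
                             relaxation = 0.8, train_fraction = 0.7,
                             seed = 1L) {
  structure(list(
    target_accuracy = assert_fraction(target_accuracy, "target_accuracy",
                                      0, 1, lo_open = FALSE),
    max_iterations = assert_count(max_iterations, "max_iterations"),
    C = assert_fraction(C, "C", 0, Inf, lo_open = TRUE),
    epsilon = assert_fraction(epsilon, "epsilon", 0, Inf),
    gamma = if (!is.null(gamma)) assert_fraction(gamma, "gamma", 0, Inf,
                                                 lo_open = TRUE),
    relaxation = assert_fraction(relaxation, "relaxation", 0, 1,
                                 lo_open = TRUE, hi_open = TRUE),
    train_fraction = assert_fraction(train_fraction, "train_fraction",
                                     0, 1, lo_open = TRUE, hi_open = TRUE),
    seed = assert_count(seed, "seed", min = 0L)),
    class = "selection_config")
}

# RBF width by the median pairwise distance heuristic (subsampled for speed).
median_distance_gamma <- function(X, max_n = 200L) {
  if (nrow(X) > max_n) X <- X[seq(1L, nrow(X), length.out = max_n), ,
                              drop = FALSE]
  rho <- stats::median(stats::dist(X))
  if (!is.finite(rho) || rho == 0) return(1 / max(1L, ncol(X)))
  1 / (2 * rho^2)
}

#' SVR fitness of a candidate feature subset
#'
#' Encodes the class labels as consecutive integers, fits an
#' epsilon-insensitive RBF-kernel support-vector regressor on a seeded
#' stratified split, rounds its real-valued predictions to the nearest
#' valid label (clipping to the label range), and returns the held-out
#' accuracy.
#'
#' @param fm A [feature_matrix()] already restricted to the candidate
#'   columns.
#' @param labels Class labels; defaults to the matrix's own.
#' @param cfg A [selection_config()].
#' @return Held-out accuracy as a fraction in `[0, 1]`.
#' @export
svr_fitness <- function(fm, labels = fm$labels, cfg = selection_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(cfg, "selection_config"))
  if (ncol(fm$values) == 0L) stop("empty candidate set", call. = FALSE)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("need at least two classes", call. = FALSE)
  y <- as.integer(labels)
  sp <- stratified_indices(labels, cfg$train_fraction, cfg$seed)
  Xtr <- fm$values[sp$train, , drop = FALSE]
  Xte <- fm$values[sp$test, , drop = FALSE]
  gamma <- if (is.null(cfg$gamma)) median_distance_gamma(Xtr) else cfg$gamma
  fit <- e1071::svm(Xtr, y[sp$train], type = "eps-regression",
                    kernel = "radial", cost = cfg$C, epsilon = cfg$epsilon,
                    gamma = gamma, scale = FALSE)
  pred <- round(stats::predict(fit, Xte))
  pred <- pmin(pmax(pred, 1L), nlevels(labels))
  mean(pred == y[sp$test])
}

#' Skewness-controlled, SVR-validated feature selection
#'
#' Stage one thresholds the per-column means at the Pearson skewness of
#' their distribution ([skew_threshold()]). Stage two validates the
#' candidate set with an SVR fitness score ([svr_fitness()]); while the
#' score is below `target_accuracy` and iterations remain, the threshold is
#' relaxed multiplicatively (sign-aware, so it never rises), admitting more
#' columns, and fitness is re-evaluated. The best-fitness candidate set
#' seen is returned.
#'
#' @param fm A [feature_matrix()] (typically the SEM-thresholded fusion
#'   output).
#' @param labels Class labels; defaults to the matrix's own.
#' @param cfg A [selection_config()].
#' @param n_features Optional cap emulating a fixed-size sweep: when given,
#'   the iterative procedure is bypassed and the `n_features` columns with
#'   the largest means are selected, with a single fitness evaluation.
#' @return An object of class `selection_result`: `selected_idx`, `skew`,
#'   `iterations_run`, `fitness_trace`, `candidate_trace` (per-iteration
#'   candidate index sets), `converged`, and `selected` (the restricted
#'   `feature_matrix`, `source_tag = "selected"`).
#' @export
select_features <- function(fm, labels = fm$labels, cfg = selection_config(),
                            n_features = NULL) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(cfg, "selection_config"))
  fm$labels <- droplevels(as.factor(labels))
  if (!is.null(n_features)) {
    n_features <- assert_count(n_features, "n_features")
    n_features <- min(n_features, ncol(fm$values))
    cm <- column_means(fm)
    idx <- order(cm, decreasing = TRUE)[seq_len(n_features)]
    idx <- sort(idx)
    fit <- svr_fitness(fm_subset_columns(fm, idx), cfg = cfg)
    return(structure(list(selected_idx = idx, skew = NA_real_,
                          iterations_run = 1L, fitness_trace = fit,
                          converged = fit >= cfg$target_accuracy,
                          selected = fm_subset_columns(fm, idx, "selected")),
                     class = "selection_result"))
  }
  st <- skew_threshold(fm)
  cm <- st$column_summary
  thr <- st$skew
  trace <- numeric(0)
  cand_trace <- list()
  best <- NULL
  best_fit <- -Inf
  converged <- FALSE
  for (i in seq_len(cfg$max_iterations)) {
    candidates <- unname(which(cm >= thr))
    if (!length(candidates)) {
      # threshold above every mean: admit the strongest column so the
      # fitness loop can proceed
      candidates <- unname(which.max(cm))
    }
    cand_trace[[i]] <- candidates
    fit <- svr_fitness(fm_subset_columns(fm, candidates), cfg = cfg)
    trace <- c(trace, fit)
    if (fit > best_fit) {
      best_fit <- fit
      best <- candidates
    }
    if (fit >= cfg$target_accuracy) {
      converged <- TRUE
      break
    }
    thr <- if (thr >= 0) thr * cfg$relaxation else thr / cfg$relaxation
  }
  structure(list(selected_idx = best, skew = st$skew,
                 iterations_run = length(trace), fitness_trace = trace,
                 candidate_trace = cand_trace, converged = converged,
                 selected = fm_subset_columns(fm, best, "selected")),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(paste0("<selection_result> %d columns selected after %d ",
                     "iteration(s); best fitness %.3f (%s)\n"),
              length(x$selected_idx), x$iterations_run,
              max(x$fitness_trace),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
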