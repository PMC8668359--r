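# Naive, loop-based re-implementations used as independent oracles.
# Deliberately slow and literal; they share no code with the package.

naive_sd <- function(v) {
  m <- sum(v) / length(v)
  acc <- 0
  for (x in v) acc <- acc + (x - m)^2
  sqrt(acc / (length(v) - 1))
}

naive_sem <- function(v) naive_sd(v) / sqrt(length(v))

naive_pearson_skew <- function(v) {
  m <- sum(v) / length(v)
  sv <- sort(v)
  n <- length(v)
  med <- if (n %% 2 == 1) sv[(n + 1) / 2] else (sv[n / 2] + sv[n / 2 + 1]) / 2
  3 * (m - med) / naive_sd(v)
}

naive_metrics <- function(conf) {
  K <- nrow(conf)
  recalls <- precisions <- numeric(K)
  for (k in seq_len(K)) {
    recalls[k] <- conf[k, k] / sum(conf[k, ])
    cs <- sum(conf[, k])
    precisions[k] <- if (cs > 0) conf[k, k] / cs else 0
  }
  R <- 100 * mean(recalls)
  P <- 100 * mean(precisions)
  tp <- 0
  for (k in seq_len(K)) tp <- tp + conf[k, k]
  list(recall = R, precision = P, fnr = 100 - R,
       accuracy = 100 * tp / sum(conf),
       f1 = 2 * P * R / (P + R))
}

# Random 8-bit raster for operator property tests.
random_raster <- function(h = 5, w = 4, c = 3) {
  array(sample.int(256, h * w * c, replace = TRUE) - 1L, c(h, w, c))
}

# Image set with prescribed per-class counts of tiny random images.
raster_set <- function(counts, h = 8, w = 8) {
  recs <- list()
  for (cls in names(counts)) {
    for (i in seq_len(counts[[cls]])) {
      recs[[length(recs) + 1L]] <- image_record(
        random_raster(h, w), class_label = cls,
        id = sprintf("%s_%03d", cls, i))
    }
  }
  image_set(recs)
}

# Seeded label permutation that leaves the caller's RNG untouched.
with_seed_shuffle <- function(labels, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 1000L)
  sample(labels)
}

# Row subset keeping the feature_matrix contract (test-local convenience).
fm_subset_rows_for_test <- function(fm, idx) {
  feature_matrix(fm$values[idx, , drop = FALSE],
                 as.character(fm$labels)[idx],
                 column_ids = fm$column_ids, source_tag = fm$source_tag)
}

# Feature matrix whose column means are exactly `means`.
fm_with_means <- function(means, n = 4) {
  vals <- matrix(rep(means, each = n), n, length(means))
  vals <- vals + rep(c(-0.5, 0.5), length.out = n)  # mean-preserving spread
  feature_matrix(vals, rep(c("a", "b"), length.out = n))
}
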