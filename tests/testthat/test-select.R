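test_that("Pearson skewness matches hand-derived values", {
  expect_equal(pearson_skewness(1:5), 0)
  # mean 4, median 3, s^2 = 50/4
  expect_equal(pearson_skewness(c(1, 2, 3, 4, 10)),
               3 * (4 - 3) / sqrt(50 / 4), tolerance = 1e-12)
  expect_equal(pearson_skewness(c(1, 2, 3, 4, 10)), 0.8485, tolerance = 1e-4)
  expect_error(pearson_skewness(rep(2, 5)), "degenerate")
  expect_error(pearson_skewness(3), "at least 2")
})

test_that("the skewness threshold selects by column mean", {
  st <- skew_threshold(fm_with_means(c(1, 2, 3, 4, 10)))
  expect_equal(st$skew, 0.8485, tolerance = 1e-4)
  expect_equal(st$candidates, 1:5)  # every mean is >= 0.8485

  st <- skew_threshold(fm_with_means(c(0.1, 0.2, 5)))
  expect_equal(st$skew, 3 * (mean(c(0.1, 0.2, 5)) - 0.2) / sd(c(0.1, 0.2, 5)),
               tolerance = 1e-12)
  expect_equal(st$candidates, 3L)   # only the 5-mean column clears 1.678

  # symmetric means: skew 0, candidates are the nonnegative-mean columns
  st <- skew_threshold(fm_with_means(c(-2, -1, 0, 1, 2)))
  expect_equal(st$skew, 0)
  expect_equal(st$candidates, 3:5)

  expect_warning(st <- skew_threshold(fm_with_means(c(4, 4, 4))),
                 "degenerate")
  expect_equal(st$candidates, 1:3)
})

test_that("skewness and thresholding agree with a naive oracle", {
  set.seed(55)
  for (i in 1:25) {
    d <- sample(3:15, 1)
    fm <- feature_matrix(matrix(rexp(6 * d), 6, d), rep_len(c("a", "b"), 6))
    st <- skew_threshold(fm)
    cm <- vapply(seq_len(d), function(j) sum(fm$values[, j]) / 6, numeric(1))
    expect_equal(st$skew, naive_pearson_skew(cm), tolerance = 1e-12)
    expect_equal(st$candidates, which(cm >= naive_pearson_skew(cm)))
  }
})

test_that("SVR fitness separates what is separable and not what is not", {
  hi <- vapply(1:10, function(s) {
    out <- make_synthetic_features(
      synthetic_feature_spec(50, 2, 4, 4, separation = 10, seed = s))
    svr_fitness(out$features, cfg = selection_config(seed = s))
  }, numeric(1))
  expect_gte(mean(hi), 0.95)

  null_acc <- vapply(1:10, function(s) {
    out <- make_synthetic_features(
      synthetic_feature_spec(50, 2, 4, 4, separation = 10, seed = s))
    fm <- out$features
    fm$labels <- with_seed_shuffle(fm$labels, s)
    svr_fitness(fm, cfg = selection_config(seed = s))
  }, numeric(1))
  expect_lt(abs(mean(null_acc) - 0.5), 0.12)

  noise_acc <- vapply(1:10, function(s) {
    out <- make_synthetic_features(
      synthetic_feature_spec(50, 2, 0, 1, separation = 0, seed = s))
    svr_fitness(out$features, cfg = selection_config(seed = s))
  }, numeric(1))
  expect_lt(abs(mean(noise_acc) - 0.5), 0.12)
})

test_that("SVR fitness validates its inputs", {
  out <- make_synthetic_features(synthetic_feature_spec(10, 2, 2, 2, seed = 1))
  one_class <- fm_subset_rows_for_test(out$features, 1:10)
  expect_error(svr_fitness(one_class), "two classes")
  expect_error(svr_fitness(fm_subset_columns(out$features, integer(0))),
               "empty candidate")
})

test_that("selection converges immediately when the target is trivial", {
  out <- make_synthetic_features(synthetic_feature_spec(20, 3, 4, 8, seed = 2))
  sr <- select_features(out$features,
                        cfg = selection_config(target_accuracy = 0, seed = 2))
  expect_true(sr$converged)
  expect_equal(sr$iterations_run, 1L)
  expect_length(sr$fitness_trace, 1L)
})

test_that("inseparable data exhausts all iterations unconverged", {
  out <- make_synthetic_features(
    synthetic_feature_spec(30, 3, 2, 10, separation = 0, seed = 5))
  sr <- select_features(out$features, cfg = selection_config(seed = 5))
  expect_false(sr$converged)
  expect_equal(sr$iterations_run, 5L)
  expect_length(sr$fitness_trace, 5L)
})

test_that("candidate sets relax monotonically and contain the selection", {
  for (s in c(3, 17)) {
    out <- make_synthetic_features(
      synthetic_feature_spec(40, 3, 6, 18, separation = 2, seed = s))
    sr <- select_features(out$features, cfg = selection_config(seed = s))
    for (i in seq_len(sr$iterations_run - 1L)) {
      expect_true(all(sr$candidate_trace[[i]] %in% sr$candidate_trace[[i + 1]]))
    }
    best_iter <- which.max(sr$fitness_trace)
    expect_identical(sr$selected_idx, sr$candidate_trace[[best_iter]])
    expect_true(all(sr$selected_idx %in% seq_len(ncol(out$features$values))))
    expect_lte(sr$iterations_run, 5L)
  }
})

test_that("selection enriches informative columns beyond their base rate", {
  frac <- vapply(1:20, function(s) {
    out <- make_synthetic_features(
      synthetic_feature_spec(100, 3, 8, 32, separation = 3, seed = s))
    sr <- select_features(out$features, cfg = selection_config(seed = s))
    mean(sr$selected_idx %in% out$informative_idx)
  }, numeric(1))
  expect_gt(mean(frac), 8 / 40)
})

test_that("the fixed-size cap selects the top-mean columns", {
  fm <- fm_with_means(c(5, 1, 4, 0.5, 3), n = 8)
  sr <- select_features(fm, cfg = selection_config(seed = 1), n_features = 3)
  expect_equal(sr$selected_idx, c(1L, 3L, 5L))
  expect_length(sr$fitness_trace, 1L)
})
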