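make_blobs <- function(n_per_class = 20, n_classes = 3, sep = 8, seed = 1) {
  make_synthetic_features(
    synthetic_feature_spec(n_per_class, n_classes, 4, 4, separation = sep,
                           seed = seed))$features
}

test_that("the stratified holdout is an exact, proportion-preserving split", {
  fm <- make_blobs(20, 5, seed = 2)  # 100 samples
  sp <- split_holdout(fm, ratio = 0.7, seed = 7)
  expect_equal(nrow(sp$train$values), 70L)
  expect_equal(nrow(sp$test$values), 30L)
  expect_equal(sort(c(sp$train_idx, sp$test_idx)), 1:100)
  expect_equal(unname(table(sp$train$labels)), array(rep(14L, 5)),
               ignore_attr = TRUE)
  sp2 <- split_holdout(fm, ratio = 0.7, seed = 7)
  expect_identical(sp$train_idx, sp2$train_idx)

  expect_error(split_holdout(fm, ratio = 1.0), "ratio")
  tiny <- fm_subset_rows_for_test(fm, c(1, 21, 22))
  expect_error(split_holdout(tiny), "offending class")
})

test_that("every sample lands in exactly one CV test fold", {
  labels <- factor(rep(sprintf("C%d", 1:5), each = 10))
  folds <- dermafuse:::stratified_folds(labels, 10, seed = 3)
  expect_equal(sort(unique(folds)), 1:10)
  expect_equal(unname(table(folds)), array(rep(5L, 10)), ignore_attr = TRUE)
  # stratification: each fold holds one sample of each class
  for (f in 1:10) {
    expect_equal(unname(table(labels[folds == f])), array(rep(1L, 5)),
                 ignore_attr = TRUE)
  }
})

test_that("metrics reproduce the hand-worked confusion examples", {
  ident <- diag(c(10, 20, 30))
  m <- compute_metrics(ident)
  expect_equal(m$recall, 100)
  expect_equal(m$precision, 100)
  expect_equal(m$accuracy, 100)
  expect_equal(m$f1, 100)
  expect_equal(m$fnr, 0)

  conf <- matrix(c(8, 4, 2, 6), 2)  # rows (8,2) / (4,6)
  m <- compute_metrics(conf)
  expect_equal(m$recall, 70)
  expect_equal(m$accuracy, 70)
  expect_equal(m$precision, (100 * 8 / 12 + 100 * 6 / 8) / 2)
  expect_equal(m$precision, 70.83, tolerance = 1e-3)
  expect_equal(m$fnr, 30)

  expect_error(compute_metrics(matrix(0, 0, 0)), "square")
  expect_error(compute_metrics(matrix(0, 2, 2)), "empty")
})

test_that("metrics agree with a naive oracle and FNR identity is exact", {
  set.seed(77)
  for (i in 1:30) {
    K <- sample(2:6, 1)
    conf <- matrix(rpois(K * K, 3) + diag(K) * rpois(K, 10), K)
    m <- compute_metrics(conf)
    o <- naive_metrics(conf)
    for (f in names(o)) expect_equal(m[[f]], o[[f]], tolerance = 1e-9)
    expect_equal(m$fnr + m$recall, 100, tolerance = 1e-12)  # pre-rounding
  }
})

test_that("macro one-vs-rest AUC matches an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(5)
  labels <- factor(rep(c("a", "b", "c"), each = 15))
  scores <- matrix(rnorm(45 * 3), 45, 3, dimnames = list(NULL, levels(labels)))
  scores[cbind(1:45, as.integer(labels))] <-
    scores[cbind(1:45, as.integer(labels))] + 1.5
  mine <- dermafuse:::macro_auc(labels, scores)
  ref <- mean(vapply(levels(labels), function(cl) {
    as.numeric(pROC::auc(pROC::roc(labels == cl, scores[, cl],
                                   quiet = TRUE, direction = "<")))
  }, numeric(1)))
  expect_equal(mine, ref, tolerance = 1e-9)
})

test_that("cross-validation attains the bounds on easy and null data", {
  fm <- make_blobs(20, 3, sep = 30, seed = 4)
  cv <- cross_validate(fm, classifier_config("lsvm"), k = 10, seed = 4)
  expect_equal(cv$metrics$accuracy, 100)
  expect_equal(cv$metrics$fnr, 0)
  expect_equal(sum(cv$confusion), 60)  # mass conservation

  null_fm <- fm
  null_fm$labels <- with_seed_shuffle(fm$labels, 9)
  accs <- vapply(1:5, function(s) {
    cross_validate(null_fm, classifier_config("lsvm"), k = 5,
                   seed = s)$metrics$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 100 / 3), 12)
})

test_that("fold reduction warns when a class is smaller than k", {
  fm <- make_blobs(5, 3, seed = 6)
  expect_warning(cv <- cross_validate(fm, classifier_config("lsvm"), k = 10,
                                      seed = 1),
                 "reducing folds")
  expect_equal(cv$k, 5L)
})

test_that("the ten-classifier zoo beats chance on separable data", {
  # 60 per class so even the coarse k=100 neighbourhood is informative
  fm <- make_blobs(60, 3, sep = 8, seed = 11)
  rep <- run_zoo(fm, protocol = "cv", k = 5, seed = 11)
  expect_equal(nrow(rep$table), 10L)
  expect_setequal(rep$table$classifier,
                  c("lsvm", "qsvm", "csvm", "mgsvm", "cosine_knn",
                    "coarse_knn", "wknn", "esknn", "ebt", "esd"))
  expect_true(all(rep$table$accuracy > 100 / 3))
  expect_equal(sum(rep$table$best), 1L)
  expect_equal(rep$table$classifier[rep$table$best],
               rep$table$classifier[which.max(rep$table$accuracy)])
  # per-classifier confusion mass equals the sample count
  for (conf in rep$confusions) expect_equal(sum(conf), 180)
  # AUC and percentage ranges
  expect_true(all(rep$table$auc >= 0 & rep$table$auc <= 1))
  pct <- unlist(rep$table[c("recall", "precision", "fnr", "accuracy", "f1")])
  expect_true(all(pct >= 0 & pct <= 100))
})

test_that("zoo runs are reproducible and validate their inputs", {
  fm <- make_blobs(10, 2, seed = 12)
  zoo <- list(classifier_config("lsvm"), classifier_config("wknn"),
              classifier_config("ebt", seed = 3))
  r1 <- run_zoo(fm, zoo = zoo, protocol = "holdout", seed = 5)
  r2 <- run_zoo(fm, zoo = zoo, protocol = "holdout", seed = 5)
  r1$table$time_sec <- r2$table$time_sec <- NULL
  expect_identical(r1$table, r2$table)
  expect_equal(nrow(r1$table), 3L)

  expect_error(run_zoo(fm, zoo = list()), "empty")
  expect_error(run_zoo(fm, zoo = list(classifier_config("lsvm"),
                                      classifier_config("lsvm"))),
               "duplicate")
  expect_error(classifier_config("madeup"), "arg")
})

test_that("a single-classifier zoo yields a single-row report", {
  fm <- make_blobs(10, 2, seed = 13)
  rep <- run_zoo(fm, zoo = list(classifier_config("cosine_knn")),
                 protocol = "cv", k = 5, seed = 13)
  expect_equal(nrow(rep$table), 1L)
  expect_true(rep$table$best)
})
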