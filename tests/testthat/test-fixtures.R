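test_that("synthetic feature matrices honour the shape contract and seed", {
  spec <- synthetic_feature_spec(10, 3, d_informative = 4, d_noise = 6,
                                 seed = 42)
  out <- make_synthetic_features(spec)
  expect_equal(dim(out$features$values), c(30L, 10L))
  expect_equal(unname(table(out$labels)), array(rep(10L, 3)),
               ignore_attr = TRUE)
  expect_equal(out$informative_idx, 1:4)

  again <- make_synthetic_features(spec)
  expect_identical(out$features$values, again$features$values)

  other <- make_synthetic_features(
    synthetic_feature_spec(10, 3, 4, 6, seed = 43))
  expect_false(identical(out$features$values, other$features$values))
})

test_that("invalid feature specs are rejected", {
  expect_error(synthetic_feature_spec(10, 1, 4, 6), "n_classes")
  expect_error(synthetic_feature_spec(10, 3, 0, 0), "at least one feature")
  expect_error(synthetic_feature_spec(10, 3, 4, 6, separation = -1),
               "separation")
})

test_that("zero separation yields chance-level linear classification", {
  # Monte-Carlo under the null: pooled CV accuracy of a linear SVM over
  # 20 seeds should sit at 1/n_classes within binomial noise
  accs <- vapply(1:20, function(s) {
    out <- make_synthetic_features(
      synthetic_feature_spec(20, 3, 2, 6, separation = 0, seed = s))
    cv <- cross_validate(out$features, classifier_config("lsvm"), k = 5,
                         seed = s)
    cv$metrics$accuracy
  }, numeric(1))
  # 20 x 60 = 1200 pooled predictions; 5 SE of a binomial proportion ~ 7 pts
  expect_lt(abs(mean(accs) - 100 / 3), 7.5)
})

test_that("informative effect size grows monotonically with separation", {
  effect <- function(sep) {
    mean(vapply(1:5, function(s) {
      out <- make_synthetic_features(
        synthetic_feature_spec(30, 3, 4, 4, separation = sep, seed = s))
      X <- out$features$values[, out$informative_idx, drop = FALSE]
      g <- split(seq_along(out$labels), out$labels)
      cm <- vapply(g, function(i) colMeans(X[i, , drop = FALSE]), numeric(4))
      mean(apply(cm, 1, function(r) max(r) - min(r)))
    }, numeric(1)))
  }
  effects <- vapply(c(0, 1, 3, 6), effect, numeric(1))
  expect_true(all(diff(effects) > 0))
})

test_that("synthetic images are labelled, bounded, and seed-deterministic", {
  spec <- synthetic_image_spec(5, 7, 64, 64, seed = 3)
  iset <- make_synthetic_images(spec)
  expect_equal(length(iset), 35L)
  expect_equal(sort(unique(image_labels(iset))), sprintf("C%d", 1:7))
  px <- iset$records[[1]]$pixels
  expect_equal(dim(px), c(64L, 64L, 3L))
  expect_true(min(px) >= 0 && max(px) <= 255)

  again <- make_synthetic_images(spec)
  for (i in seq_len(length(iset))) {
    expect_identical(iset$records[[i]]$pixels, again$records[[i]]$pixels)
  }
})

test_that("distinct classes use distinct generator parameters", {
  pars <- dermafuse:::class_image_params(7)
  expect_equal(anyDuplicated(pars$radius), 0)
  expect_equal(anyDuplicated(pars$hue), 0)
})

test_that("feature CSV and PNG-tree round trips preserve content", {
  out <- make_synthetic_features(synthetic_feature_spec(5, 2, 2, 2, seed = 9))
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(out$features, f)
  back <- read_feature_csv(f)
  expect_equal(back$values, out$features$values, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(as.character(back$labels), as.character(out$features$labels))
  expect_equal(back$column_ids, out$features$column_ids)

  iset <- make_synthetic_images(synthetic_image_spec(2, 3, 16, 16, seed = 4))
  d <- withr::local_tempdir()
  write_image_set(iset, d)
  back <- read_image_set(d)
  expect_equal(length(back), length(iset))
  expect_equal(sort(image_labels(back)), sort(image_labels(iset)))
  orig <- iset$records[order(vapply(iset$records, `[[`, character(1), "id"))]
  got <- back$records[order(vapply(back$records, `[[`, character(1), "id"))]
  for (i in seq_along(orig)) {
    expect_identical(got[[i]]$pixels, orig[[i]]$pixels)
  }
})
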