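test_that("flips and rotation act as defined on a 2x2 raster", {
  m <- array(c(1L, 3L, 2L, 4L), c(2, 2, 1))  # rows: (1,2) / (3,4)
  expect_equal(flip_ud(m)[, , 1], matrix(c(3L, 1L, 4L, 2L), 2))
  expect_equal(flip_lr(m)[, , 1], matrix(c(2L, 4L, 1L, 3L), 2))
  # counter-clockwise quarter turn: rows become (2,4) / (1,3)
  expect_equal(rotate90(m)[, , 1], matrix(c(2L, 1L, 4L, 3L), 2))
})

test_that("operator group laws hold and channels stay unmixed", {
  set.seed(101)
  for (i in 1:50) {
    x <- random_raster(sample(2:7, 1), sample(2:7, 1))
    expect_identical(flip_ud(flip_ud(x)), x)
    expect_identical(flip_lr(flip_lr(x)), x)
    expect_identical(rotate90(rotate90(rotate90(rotate90(x)))), x)
    expect_identical(flip_lr(flip_ud(x)), flip_ud(flip_lr(x)))
    # per-channel action: each channel transformed independently
    for (ch in 1:3) {
      expect_identical(flip_ud(x)[, , ch], flip_ud(x[, , ch]))
    }
  }
})

test_that("rotation swaps height and width and respects direction", {
  x <- random_raster(2, 3)
  expect_equal(dim(rotate90(x)), c(3L, 2L, 3L))
  cw <- rotate90(x, dir = "cw")
  ccw <- rotate90(x)
  expect_identical(cw, flip_ud(flip_lr(ccw)))  # cw = 180-degree of ccw
})

test_that("operators preserve the pixel multiset per channel", {
  set.seed(7)
  for (i in 1:20) {
    x <- random_raster(6, 5)
    for (f in list(flip_ud, flip_lr, rotate90)) {
      y <- f(x)
      for (ch in 1:3) {
        expect_equal(sort(as.vector(y[, , ch])), sort(as.vector(x[, , ch])))
      }
    }
  }
})

test_that("balancing plans hit the target exactly", {
  plan <- plan_balancing(c(A = 115), 6000, seed = 1)
  expect_equal(unname(planned_class_sizes(plan)), 6000L)

  plan <- plan_balancing(c(A = 6000), 6000, seed = 1)
  expect_equal(nrow(plan$classes$A$augment), 0L)
  expect_equal(plan$classes$A$keep, 1:6000)

  counts <- c(NV = 6705, MEL = 1113, BKL = 1099, BCC = 514, AKIEC = 327,
              VASC = 142, DF = 115)
  plan <- plan_balancing(counts, 6000, seed = 1)
  expect_equal(unname(planned_class_sizes(plan)), rep(6000L, 7))
  expect_equal(sum(planned_class_sizes(plan)), 42000L)
  # surplus class is downsampled, not augmented
  expect_equal(length(plan$classes$NV$keep), 6000L)
  expect_equal(nrow(plan$classes$NV$augment), 0L)

  expect_error(plan_balancing(c(A = 10), 0), "target_per_class")
  expect_error(plan_balancing(c(A = 0), 10), ">= 1")
})

test_that("no operation chain repeats for the same source image", {
  plan <- plan_balancing(c(A = 3), 200, seed = 2)
  aug <- plan$classes$A$augment
  expect_equal(anyDuplicated(paste(aug$source, aug$chain)), 0L)
})

test_that("plans are deterministic under a fixed seed", {
  p1 <- plan_balancing(c(A = 5, B = 40), 30, seed = 11)
  p2 <- plan_balancing(c(A = 5, B = 40), 30, seed = 11)
  expect_identical(p1, p2)
  p3 <- plan_balancing(c(A = 5, B = 40), 30, seed = 12)
  expect_false(identical(p1, p3))
})

test_that("executing a plan reproduces it faithfully", {
  iset <- raster_set(c(A = 2))
  empty <- structure(list(classes = list(), target_per_class = 2L, seed = 1L),
                     class = "augmentation_plan")
  expect_identical(apply_plan(iset, empty)$records, iset$records)

  one_ud <- structure(list(classes = list(A = list(
    keep = 1:2,
    augment = data.frame(source = 1L, chain = "ud"),
    original_count = 2L)), target_per_class = 3L, seed = 1L),
    class = "augmentation_plan")
  out <- apply_plan(iset, one_ud)
  expect_equal(length(out), 3L)
  expect_identical(out$records[[3]]$pixels, flip_ud(iset$records[[1]])$pixels)
  expect_equal(out$records[[3]]$provenance, "ud")

  dangling <- structure(list(classes = list(A = list(
    keep = 1:2, augment = data.frame(source = 5L, chain = "lr"),
    original_count = 2L)), target_per_class = 3L, seed = 1L),
    class = "augmentation_plan")
  expect_error(apply_plan(iset, dangling), "image 5 of class 'A'")
})

test_that("a scaled imbalanced scenario balances every class exactly", {
  counts <- c(NV = 67, MEL = 11, BKL = 11, BCC = 5, AKIEC = 3, VASC = 1,
              DF = 1)
  set.seed(33)
  iset <- raster_set(counts)
  plan <- plan_balancing(counts, 60, seed = 3)
  out <- apply_plan(iset, plan)
  expect_equal(unname(table(image_labels(out))), array(rep(60L, 7)),
               ignore_attr = TRUE)
  expect_equal(length(out), 420L)
  # augmented records carry their chains as provenance
  prov <- vapply(out$records, `[[`, character(1), "provenance")
  expect_true(any(prov != "original"))
  expect_true(all(grepl("^original$|^(rot90|lr|ud)(\\+(rot90|lr|ud))*$",
                        prov)))
})
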