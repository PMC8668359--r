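#' Specification for a synthetic class-blob feature matrix
#'
#' Describes a Gaussian class-blob dataset: each class has a distinct mean in
#' an informative subspace, padded with pure-noise columns that carry no class
#' signal. This stands in for deep features when exercising fusion, selection
#' and evaluation without any image data.
#'
#' @param n_per_class Samples per class.
#' @param n_classes Number of classes (>= 2).
#' @param d_informative Number of class-informative columns.
#' @param d_noise Number of label-independent standard-normal columns.
#' @param separation Euclidean distance between class means in the informative
#'   subspace, in units of the within-class noise SD (which is 1). Zero gives
#'   a null dataset with no class signal anywhere.
#' @param nonnegative If `TRUE`, a softplus transform is applied so values
#'   emulate nonnegative ReLU-derived activations.
#' @param seed Integer RNG seed; identical specs give bit-identical data.
#' @return An object of class `synthetic_feature_spec`.
#' @export
synthetic_feature_spec <- function(n_per_class, n_classes, d_informative,
                                   d_noise, separation = 3, nonnegative = FALSE,
                                   seed = 1L) {
  spec <- list(
    n_per_class = assert_count(n_per_class, "n_per_class"),
    n_classes = assert_count(n_classes, "n_classes", min = 2L),
    d_informative = assert_count(d_informative, "d_informative", min = 0L),
    d_noise = assert_count(d_noise, "d_noise", min = 0L),
    separation = assert_fraction(separation, "separation", 0, Inf),
    nonnegative = isTRUE(nonnegative),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (spec$d_informative + spec$d_noise < 1L) {
    stop("need at least one feature column", call. = FALSE)
  }
  structure(spec, class = "synthetic_feature_spec")
}

#' Generate a synthetic feature matrix with known structure
#'
#' Draws `n_per_class` samples per class. Informative columns are Gaussian
#' with class-dependent means placed (near-)orthogonally at pairwise distance
#' `separation`; noise columns are i.i.d. standard normal, independent of the
#' labels. The informative column indices are returned so selection methods
#' can be scored against ground truth.
#'
#' @param spec A [synthetic_feature_spec()].
#' @return A list with `features` (a [feature_matrix()]), `labels` (factor,
#'   same as `features$labels`), and `informative_idx` (integer vector).
#' @examples
#' out <- make_synthetic_features(
#'   synthetic_feature_spec(10, 3, d_informative = 4, d_noise = 6, seed = 42))
#' dim(out$features$values)  # 30 x 10
#' @export
make_synthetic_features <- function(spec) {
  stopifnot(inherits(spec, "synthetic_feature_spec"))
  n <- spec$n_per_class * spec$n_classes
  d <- spec$d_informative + spec$d_noise
  with_seed(spec$seed, {
    labels <- factor(rep(sprintf("C%d", seq_len(spec$n_classes)),
                         each = spec$n_per_class))
    values <- matrix(stats::rnorm(n * d), n, d)
    if (spec$d_informative > 0L && spec$separation > 0) {
      # each informative column is "owned" by one class (round-robin) and
      # carries a positive mean `a` for that class, zero for the others;
      # with q = d_informative/n_classes owned columns per class the
      # between-class mean distance is a*sqrt(2q) = separation
      owner <- rep_len(seq_len(spec$n_classes), spec$d_informative)
      a <- spec$separation /
        sqrt(2 * spec$d_informative / spec$n_classes)
      mu <- matrix(0, spec$d_informative, spec$n_classes)
      mu[cbind(seq_len(spec$d_informative), owner)] <- a
      values[, seq_len(spec$d_informative)] <-
        values[, seq_len(spec$d_informative), drop = FALSE] +
        t(mu[, as.integer(labels), drop = FALSE])
    }
    if (spec$nonnegative) values <- log1p(exp(values))
    ids <- c(sprintf("inf%03d", seq_len(spec$d_informative)),
             sprintf("noise%03d", seq_len(spec$d_noise)))
    list(features = feature_matrix(values, labels, column_ids = ids,
                                   source_tag = "synthetic"),
         labels = labels,
         informative_idx = seq_len(spec$d_informative))
  })
}

#' Specification for a synthetic labelled image set
#'
#' @param n_per_class Images per class.
#' @param n_classes Number of classes.
#' @param height,width Image size in pixels (>= 8).
#' @param seed Integer RNG seed.
#' @return An object of class `synthetic_image_spec`.
#' @export
synthetic_image_spec <- function(n_per_class, n_classes, height = 64,
                                 width = 64, seed = 1L) {
  spec <- list(
    n_per_class = assert_count(n_per_class, "n_per_class"),
    n_classes = assert_count(n_classes, "n_classes", min = 2L),
    height = assert_count(height, "height", min = 8L),
    width = assert_count(width, "width", min = 8L),
    seed = assert_count(seed, "seed", min = 0L)
  )
  structure(spec, class = "synthetic_image_spec")
}

# Deterministic per-class generator parameters: blob radius fraction and hue.
class_image_params <- function(n_classes) {
  k <- seq_len(n_classes)
  list(radius = 0.12 + 0.25 * (k - 1) / max(1, n_classes - 1),
       hue = (k - 1) / n_classes)
}

hue_to_rgb <- function(h) {
  # saturated hue wheel, value 1
  x <- abs((h * 6) %% 2 - 1)
  i <- floor(h * 6) %% 6
  rbind(c(1, 1 - x, 0), c(x, 1, 0), c(0, 1, 1 - x),
        c(0, x, 1), c(1 - x, 0, 1), c(1, 0, x))[i + 1, ]
}

#' Generate a synthetic labelled image set
#'
#' Each class is a distinct parametric family: a filled disk with a
#' class-specific radius and hue on a textured background, with per-image
#' seeded jitter of the disk centre. The images exist so augmentation and
#' feature extraction have non-degenerate, class-separable input; they make
#' no attempt at photorealistic dermoscopy.
#'
#' @param spec A [synthetic_image_spec()].
#' @return An [image_set()]; pixels are integer arrays in `[0, 255]`, 3
#'   channels.
#' @export
make_synthetic_images <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  pars <- class_image_params(spec$n_classes)
  with_seed(spec$seed, {
    records <- list()
    for (k in seq_len(spec$n_classes)) {
      cls <- sprintf("C%d", k)
      col <- hue_to_rgb(pars$hue[k])
      for (i in seq_len(spec$n_per_class)) {
        px <- array(0L, c(spec$height, spec$width, 3L))
        bg <- matrix(stats::runif(spec$height * spec$width, 0.05, 0.35),
                     spec$height, spec$width)
        cy <- spec$height * stats::runif(1, 0.35, 0.65)
        cx <- spec$width * stats::runif(1, 0.35, 0.65)
        r <- pars$radius[k] * min(spec$height, spec$width)
        dy <- matrix(seq_len(spec$height), spec$height, spec$width) - cy
        dx <- matrix(seq_len(spec$width), spec$height, spec$width,
                     byrow = TRUE) - cx
        disk <- (dy^2 + dx^2) <= r^2
        for (ch in 1:3) {
          plane <- bg
          plane[disk] <- col[ch] * stats::runif(1, 0.85, 1)
          px[, , ch] <- as.integer(round(pmin(pmax(plane, 0), 1) * 255))
        }
        records[[length(records) + 1L]] <- image_record(
          px, class_label = cls, id = sprintf("%s_%03d", cls, i))
      }
    }
    image_set(records)
  })
}
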