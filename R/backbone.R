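#' Backbone configuration for deep-feature extraction
#'
#' Describes a feature-extraction backbone: a residual network whose final
#' fully connected layer is replaced by a new head sized to the target label
#' space, with features tapped at the global average pooling layer — or a
#' fast mock backbone (a fixed seeded random projection of the flattened,
#' resized pixels) so the pipeline is testable offline in seconds.
#'
#' Training hyperparameters default to the head-training recipe used
#' throughout: SGD, learning rate 1e-4, 100 epochs, minibatch 64.
#'
#' @param architecture `"resnet50"`, `"resnet101"`, or `"mock"`.
#' @param n_classes Width of the new classification head (>= 2).
#' @param input_size Side length images are resized to before extraction;
#'   224 for the residual networks (their native receptive field), 32 for
#'   the mock.
#' @param feature_width Width of the feature tap. Fixed at 2048 for both
#'   residual networks (the global average pooling width); free for the mock.
#' @param learning_rate,epochs,minibatch,optimizer Head-training
#'   hyperparameters; only `"sgd"` is supported.
#' @param seed Seed for weight initialisation (and the mock projection).
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(architecture = c("mock", "resnet50", "resnet101"),
                            n_classes = 7L,
                            input_size = NULL,
                            feature_width = NULL,
                            learning_rate = 1e-4,
                            epochs = 100L,
                            minibatch = 64L,
                            optimizer = "sgd",
                            seed = 1L) {
  architecture <- match.arg(architecture)
  n_classes <- assert_count(n_classes, "n_classes", min = 2L)
  if (is.null(input_size)) {
    input_size <- if (architecture == "mock") 32L else 224L
  }
  input_size <- assert_count(input_size, "input_size", min = 8L)
  if (architecture %in% c("resnet50", "resnet101")) {
    if (!is.null(feature_width) && feature_width != 2048L) {
      stop("feature_width is fixed at 2048 for residual backbones",
           call. = FALSE)
    }
    feature_width <- 2048L
  } else if (is.null(feature_width)) {
    feature_width <- 32L
  }
  feature_width <- assert_count(feature_width, "feature_width")
  if (!is.numeric(learning_rate) || learning_rate <= 0) {
    stop("learning_rate must be > 0", call. = FALSE)
  }
  epochs <- assert_count(epochs, "epochs", min = 0L)
  minibatch <- assert_count(minibatch, "minibatch")
  if (!identical(tolower(optimizer), "sgd")) {
    stop("only the SGD optimizer is supported", call. = FALSE)
  }
  structure(list(architecture = architecture, n_classes = n_classes,
                 input_size = input_size, feature_width = feature_width,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 minibatch = minibatch, optimizer = "sgd",
                 seed = assert_count(seed, "seed", min = 0L)),
            class = "backbone_config")
}

#' Build a feature extractor from a backbone configuration
#'
#' Residual backbones are instantiated with seeded He-initialised weights
#' (no pretrained download); the mock backbone draws a fixed random
#' projection matrix. Both expose the same contract: a feature tap of width
#' `feature_width` and a linear softmax head of width `n_classes`.
#'
#' @param cfg A [backbone_config()].
#' @return An object of class `feature_extractor`.
#' @export
build_feature_extractor <- function(cfg) {
  stopifnot(inherits(cfg, "backbone_config"))
  ex <- list(cfg = cfg, classes = NULL,
             head = matrix(0, cfg$feature_width + 1L, cfg$n_classes))
  if (cfg$architecture == "mock") {
    d_in <- cfg$input_size^2 * 3L
    ex$projection <- with_seed(cfg$seed,
      matrix(stats::rnorm(d_in * cfg$feature_width, sd = 1 / sqrt(d_in)),
             d_in, cfg$feature_width))
  } else {
    ex$weights <- init_resnet_weights(cfg$architecture, cfg$seed)
  }
  structure(ex, class = "feature_extractor")
}

#' @export
print.feature_extractor <- function(x, ...) {
  cat(sprintf("<feature_extractor> %s: input %dx%d -> %d features -> %d classes%s\n",
              x$cfg$architecture, x$cfg$input_size, x$cfg$input_size,
              x$cfg$feature_width, x$cfg$n_classes,
              if (is.null(x$classes)) " (head untrained)" else " (head trained)"))
  invisible(x)
}

# Resize to the backbone's receptive field (bilinear) and standardize each
# channel to zero mean / unit SD within the image. Grayscale is replicated
# to three channels.
preprocess_image <- function(rec, input_size) {
  px <- rec$pixels / 255
  if (dim(px)[3] == 1L) px <- px[, , c(1L, 1L, 1L)]
  if (dim(px)[1] != input_size || dim(px)[2] != input_size) {
    px <- EBImage::resize(px, w = input_size, h = input_size)
    px <- array(px, c(input_size, input_size, 3L))
  }
  for (ch in 1:3) {
    v <- px[, , ch]
    s <- stats::sd(v)
    px[, , ch] <- if (s > 0) (v - mean(v)) / s else v - mean(v)
  }
  px
}

#' Extract deep features from an image set
#'
#' Runs each image (in input order) through the extractor's feature tap at
#' the global average pooling layer (or the mock projection), after bilinear
#' resizing to the configured input size and channel-wise standardisation.
#'
#' @param extractor A [build_feature_extractor()] result.
#' @param images An [image_set()].
#' @return A [feature_matrix()], one row per image, labels carried through,
#'   `source_tag` set to the architecture name.
#' @export
extract_features <- function(extractor, images) {
  stopifnot(inherits(extractor, "feature_extractor"),
            inherits(images, "image_set"))
  if (!length(images)) stop("empty image set", call. = FALSE)
  cfg <- extractor$cfg
  n <- length(images)
  values <- matrix(NA_real_, n, cfg$feature_width)
  for (i in seq_len(n)) {
    px <- preprocess_image(images$records[[i]], cfg$input_size)
    values[i, ] <- if (cfg$architecture == "mock") {
      # rectified random projection: nonnegative, like the ReLU-derived
      # activations the residual backbones feed into global average pooling
      pmax(as.numeric(crossprod(extractor$projection, as.numeric(px))), 0)
    } else {
      resnet_forward_features(extractor$weights, px)
    }
  }
  feature_matrix(values, image_labels(images),
                 column_ids = sprintf("%s_%04d", cfg$architecture,
                                      seq_len(cfg$feature_width)),
                 source_tag = cfg$architecture)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Fine-tune an extractor's classification head
#'
#' Replaces-and-trains the head: the linear softmax layer on top of the
#' feature tap is fit by minibatch SGD on cross-entropy using the configured
#' learning rate, epochs and batch size. Backbone weights stay frozen, so
#' the features an extractor yields are unchanged by tuning; only its
#' predictions are.
#'
#' @param extractor A [build_feature_extractor()] result.
#' @param images A labelled [image_set()] with at least two classes.
#' @param cfg Optional [backbone_config()] overriding the extractor's
#'   training hyperparameters.
#' @return A `feature_extractor` with a trained head and a `classes` field.
#' @export
fine_tune <- function(extractor, images, cfg = extractor$cfg) {
  stopifnot(inherits(extractor, "feature_extractor"))
  fm <- extract_features(extractor, images)
  y <- fm$labels
  if (nlevels(droplevels(y)) < 2L) {
    stop("fine-tuning needs at least two classes", call. = FALSE)
  }
  if (nlevels(droplevels(y)) > cfg$n_classes) {
    stop("more classes in the data than head outputs", call. = FALSE)
  }
  classes <- levels(droplevels(y))
  X <- cbind(1, fm$values)                       # bias column
  Yk <- match(as.character(y), classes)
  n <- nrow(X)
  W <- matrix(0, ncol(X), length(classes))
  if (cfg$epochs > 0L) {
    with_seed(cfg$seed + 1L, {
      for (ep in seq_len(cfg$epochs)) {
        ord <- sample.int(n)
        for (start in seq(1L, n, by = cfg$minibatch)) {
          idx <- ord[start:min(start + cfg$minibatch - 1L, n)]
          P <- softmax_rows(X[idx, , drop = FALSE] %*% W)
          Tg <- matrix(0, length(idx), length(classes))
          Tg[cbind(seq_along(idx), Yk[idx])] <- 1
          W <- W - cfg$learning_rate *
            crossprod(X[idx, , drop = FALSE], P - Tg) / length(idx)
        }
      }
    })
  }
  out <- extractor
  out$head <- W
  out$classes <- classes
  out
}

#' Predict classes with a fine-tuned extractor's head
#'
#' @param object A [fine_tune()]d `feature_extractor`.
#' @param images An [image_set()].
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.feature_extractor <- function(object, images, ...) {
  if (is.null(object$classes)) stop("head is untrained; call fine_tune()",
                                    call. = FALSE)
  fm <- extract_features(object, images)
  scores <- cbind(1, fm$values) %*% object$head
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = object$classes)
}
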