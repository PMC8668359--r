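#' Geometric augmentation operators
#'
#' The three operators used for class balancing: vertical flip (`flip_ud`,
#' row reversal), horizontal flip (`flip_lr`, column reversal), and rigid
#' 90-degree rotation (`rotate90`, transpose plus one flip). Each preserves
#' the multiset of pixel values per channel; the flips are involutions and
#' four rotations compose to the identity.
#'
#' @param img An [image_record()] or a plain `H x W (x C)` array.
#' @param dir Rotation direction, `"ccw"` (default) or `"cw"`.
#' @return The transformed image, same type as the input. For records, the
#'   provenance chain is extended (`"ud"`, `"lr"`, `"rot90"`).
#' @examples
#' m <- array(1:4, c(2, 2, 1))
#' flip_ud(m)[, , 1]    # rows reversed
#' rotate90(m)[, , 1]   # counter-clockwise quarter turn
#' @name augment-operators
NULL

apply_to_pixels <- function(img, f, tag) {
  if (inherits(img, "image_record")) {
    out <- img
    out$pixels <- f(img$pixels)
    out$provenance <- if (identical(img$provenance, "original")) tag else {
      paste(img$provenance, tag, sep = "+")
    }
    out
  } else {
    f(img)
  }
}

flip_rows <- function(px) px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
flip_cols <- function(px) px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
transpose_px <- function(px) aperm(px, c(2L, 1L, 3L))

as_3d <- function(px) {
  if (length(dim(px)) == 2L) dim(px) <- c(dim(px), 1L)
  px
}

#' @rdname augment-operators
#' @export
flip_ud <- function(img) {
  apply_to_pixels(img, function(px) {
    drop2 <- length(dim(px)) == 2L
    out <- flip_rows(as_3d(px))
    if (drop2) out <- out[, , 1]
    out
  }, "ud")
}

#' @rdname augment-operators
#' @export
flip_lr <- function(img) {
  apply_to_pixels(img, function(px) {
    drop2 <- length(dim(px)) == 2L
    out <- flip_cols(as_3d(px))
    if (drop2) out <- out[, , 1]
    out
  }, "lr")
}

#' @rdname augment-operators
#' @export
rotate90 <- function(img, dir = c("ccw", "cw")) {
  dir <- match.arg(dir)
  apply_to_pixels(img, function(px) {
    drop2 <- length(dim(px)) == 2L
    px3 <- as_3d(px)
    # ccw: transpose then reverse rows; cw: transpose then reverse columns
    out <- if (dir == "ccw") flip_rows(transpose_px(px3)) else {
      flip_cols(transpose_px(px3))
    }
    if (drop2) out <- out[, , 1]
    out
  }, "rot90")
}

#' Apply a named operation chain to an image
#'
#' @param img An [image_record()] or array.
#' @param chain Chain string, operations separated by `+`, e.g. `"rot90+lr"`;
#'   applied left to right.
#' @param dir Rotation direction passed to [rotate90()].
#' @return Transformed image.
#' @export
apply_chain <- function(img, chain, dir = "ccw") {
  for (op in strsplit(chain, "+", fixed = TRUE)[[1]]) {
    img <- switch(op,
      ud = flip_ud(img),
      lr = flip_lr(img),
      rot90 = rotate90(img, dir),
      stop("unknown operation: ", op, call. = FALSE))
  }
  img
}

# All 3^L operation chains of length L, in deterministic order.
chains_of_length <- function(L) {
  ops <- c("rot90", "lr", "ud")
  g <- do.call(expand.grid,
               c(rep(list(ops), L), stringsAsFactors = FALSE))[, rev(seq_len(L)),
                                                               drop = FALSE]
  apply(g, 1, paste, collapse = "+")
}

#' Plan class-balancing augmentation
#'
#' Builds a deterministic per-class schedule that brings every class to
#' exactly `target_per_class` images. Deficit classes are filled by applying
#' the three single operators to every original, then length-2 chains, then
#' longer ones, truncating the final round by a seeded random choice. Surplus
#' classes are randomly downsampled (seeded) to the target.
#'
#' @param class_counts Named integer vector of original per-class counts
#'   (all >= 1).
#' @param target_per_class Desired count per class (>= 1).
#' @param seed Integer seed controlling truncation and downsampling.
#' @return An object of class `augmentation_plan`: per class, `keep` (source
#'   indices retained) and `augment` (data frame of `source` index and
#'   operation `chain`).
#' @examples
#' plan <- plan_balancing(c(A = 115), target_per_class = 6000, seed = 1)
#' planned_class_sizes(plan)  # A: 6000
#' @export
plan_balancing <- function(class_counts, target_per_class, seed = 1L) {
  target_per_class <- assert_count(target_per_class, "target_per_class")
  if (!length(class_counts) || any(class_counts < 1)) {
    stop("all class counts must be >= 1", call. = FALSE)
  }
  if (is.null(names(class_counts))) {
    names(class_counts) <- sprintf("C%d", seq_along(class_counts))
  }
  classes <- list()
  with_seed(seed, {
    for (cls in names(class_counts)) {
      n <- as.integer(class_counts[[cls]])
      if (n > target_per_class) {
        keep <- sort(sample.int(n, target_per_class))
        aug <- data.frame(source = integer(), chain = character())
      } else {
        keep <- seq_len(n)
        deficit <- target_per_class - n
        aug <- data.frame(source = integer(), chain = character())
        L <- 1L
        while (deficit > 0L) {
          chains <- chains_of_length(L)
          round_df <- data.frame(
            source = rep(seq_len(n), times = length(chains)),
            chain = rep(chains, each = n))
          if (nrow(round_df) > deficit) {
            round_df <- round_df[sort(sample.int(nrow(round_df), deficit)), ]
          }
          aug <- rbind(aug, round_df)
          deficit <- deficit - nrow(round_df)
          L <- L + 1L
        }
      }
      classes[[cls]] <- list(keep = keep, augment = aug,
                             original_count = n)
    }
  })
  structure(list(classes = classes, target_per_class = target_per_class,
                 seed = as.integer(seed)),
            class = "augmentation_plan")
}

#' Planned output size per class
#' @param plan An [plan_balancing()] result.
#' @return Named integer vector: images per class after execution.
#' @export
planned_class_sizes <- function(plan) {
  stopifnot(inherits(plan, "augmentation_plan"))
  vapply(plan$classes,
         function(p) length(p$keep) + nrow(p$augment), integer(1))
}

#' @export
print.augmentation_plan <- function(x, ...) {
  sizes <- planned_class_sizes(x)
  cat(sprintf("<augmentation_plan> target %d per class, total %d\n",
              x$target_per_class, sum(sizes)))
  for (cls in names(x$classes)) {
    p <- x$classes[[cls]]
    cat(sprintf("  %s: %d originals -> keep %d + augment %d\n",
                cls, p$original_count, length(p$keep), nrow(p$augment)))
  }
  invisible(x)
}

#' Execute an augmentation plan on an image set
#'
#' @param iset An [image_set()] containing the original images.
#' @param plan An [plan_balancing()] result whose per-class source indices
#'   refer to the class's images in set order.
#' @param dir Rotation direction for `rot90` steps.
#' @return An [image_set()] with exactly `target_per_class` images in every
#'   planned class; augmented records carry their operation chain as
#'   provenance and derived ids.
#' @export
apply_plan <- function(iset, plan, dir = "ccw") {
  stopifnot(inherits(iset, "image_set"), inherits(plan, "augmentation_plan"))
  labels <- image_labels(iset)
  out <- list()
  for (cls in names(plan$classes)) {
    p <- plan$classes[[cls]]
    cls_records <- iset$records[labels == cls]
    max_ref <- max(c(p$keep, p$augment$source, 0L))
    if (max_ref > length(cls_records)) {
      stop(sprintf("plan references image %d of class '%s' but only %d exist",
                   max_ref, cls, length(cls_records)), call. = FALSE)
    }
    out <- c(out, cls_records[p$keep])
    if (nrow(p$augment)) {
      for (r in seq_len(nrow(p$augment))) {
        src <- cls_records[[p$augment$source[r]]]
        rec <- apply_chain(src, p$augment$chain[r], dir = dir)
        rec$id <- paste(src$id, gsub("\\+", "-", p$augment$chain[r]),
                        sep = "__")
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  # classes absent from the plan pass through untouched
  out <- c(out, iset$records[!labels %in% names(plan$classes)])
  image_set(out)
}

#' Serialize an augmentation plan to JSON
#' @param plan An [plan_balancing()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan_json <- function(plan, path) {
  stopifnot(inherits(plan, "augmentation_plan"))
  jsonlite::write_json(
    list(target_per_class = plan$target_per_class, seed = plan$seed,
         classes = lapply(plan$classes, function(p) {
           list(keep = p$keep, original_count = p$original_count,
                augment = p$augment)
         })),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
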