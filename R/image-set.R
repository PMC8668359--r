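#' Construct a labelled image record
#'
#' @param pixels Integer array `H x W x C` (`C` in `{1, 3}`) of values within
#'   the 8-bit range `[0, 255]`.
#' @param class_label Class of the image.
#' @param id Unique identifier within an image set.
#' @param provenance Operation history: `"original"` or a chain string such
#'   as `"rot90+lr"`.
#' @return An object of class `image_record`.
#' @export
image_record <- function(pixels, class_label, id,
                         provenance = "original") {
  if (length(dim(pixels)) == 2L) dim(pixels) <- c(dim(pixels), 1L)
  d <- dim(pixels)
  if (length(d) != 3L || !d[3] %in% c(1L, 3L)) {
    stop("pixels must be H x W x C with C in {1, 3}", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, class_label = as.character(class_label),
                 id = as.character(id), provenance = as.character(provenance)),
            class = "image_record")
}

#' Construct an image set
#'
#' A flat, ordered collection of [image_record()]s with unique ids; the
#' working container of the augmentation and extraction stages.
#'
#' @param records List of [image_record()]s.
#' @return An object of class `image_set`.
#' @export
image_set <- function(records = list()) {
  stopifnot(all(vapply(records, inherits, logical(1), "image_record")))
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate image ids", call. = FALSE)
  structure(list(records = records), class = "image_set")
}

#' @export
length.image_set <- function(x) length(x$records)

#' @export
print.image_set <- function(x, ...) {
  tab <- table(image_labels(x))
  cat(sprintf("<image_set> %d images, %d classes\n", length(x), length(tab)))
  if (length(tab)) {
    cat(paste(sprintf("  %s: %d", names(tab), tab), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Class labels of an image set
#' @param iset An [image_set()].
#' @return Character vector, one label per image in order.
#' @export
image_labels <- function(iset) {
  vapply(iset$records, `[[`, character(1), "class_label")
}

#' Write an image set as a class-per-subfolder PNG tree
#'
#' @param iset An [image_set()].
#' @param dir Output directory; one subfolder per class is created.
#' @return `dir`, invisibly.
#' @export
write_image_set <- function(iset, dir) {
  stopifnot(inherits(iset, "image_set"))
  for (rec in iset$records) {
    cls_dir <- file.path(dir, rec$class_label)
    dir.create(cls_dir, recursive = TRUE, showWarnings = FALSE)
    img <- rec$pixels / 255
    if (dim(img)[3] == 1L) img <- img[, , 1]
    png::writePNG(img, file.path(cls_dir, paste0(rec$id, ".png")))
  }
  invisible(dir)
}

#' Read an image set from a class-per-subfolder tree
#'
#' Subfolder names become class labels; PNG files are loaded as 8-bit pixel
#' arrays. Non-PNG files are skipped with a warning.
#'
#' @param dir Directory with one subfolder per class.
#' @return An [image_set()].
#' @export
read_image_set <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  classes <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  records <- list()
  for (cls in classes) {
    files <- sort(list.files(file.path(dir, cls), full.names = TRUE))
    for (f in files) {
      if (!grepl("\\.png$", f, ignore.case = TRUE)) {
        warning("skipping non-PNG file: ", f, call. = FALSE)
        next
      }
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L && dim(img)[3] == 4L) {
        img <- img[, , 1:3, drop = FALSE]  # drop alpha
      }
      px <- round(img * 255)
      records[[length(records) + 1L]] <- image_record(
        px, class_label = cls,
        id = sub("\\.png$", "", basename(f), ignore.case = TRUE))
    }
  }
  if (!length(records)) stop("no PNG images found under ", dir, call. = FALSE)
  image_set(records)
}
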