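#' Single-channel grayscale image
#'
#' A `gray_image` is a numeric matrix of pixel intensities carrying an
#' explicit intensity domain: `"raw"` values live in \[0, 255\] (as read from
#' 8-bit files), `"normalized"` values in \[0, 1\] (network input scale).
#'
#' @param pixels Numeric matrix of intensities (rows = image rows).
#' @param domain `"raw"` or `"normalized"`.
#' @return A `gray_image` object (a classed matrix with a `domain` attribute).
#' @examples
#' img <- gray_image(matrix(128, 8, 8), "raw")
#' image_domain(img)
#' @export
gray_image <- function(pixels, domain = c("raw", "normalized")) {
  domain <- match.arg(domain)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stopf("pixels must be a numeric matrix (single channel)")
  hi <- if (domain == "raw") 255 else 1
  rng <- range(pixels)
  if (rng[1] < -1e-9 || rng[2] > hi + 1e-9)
    stopf("pixel values outside declared %s domain [0, %s]", domain, hi)
  structure(pixels, domain = domain, class = c("gray_image", "matrix"))
}

#' @rdname gray_image
#' @param x A `gray_image`.
#' @export
image_domain <- function(x) {
  d <- attr(x, "domain")
  if (is.null(d)) "raw" else d
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d, %s domain, range [%.3f, %.3f]>\n",
              nrow(x), ncol(x), image_domain(x), min(x), max(x)))
  invisible(x)
}

#' Class names of the six hESC morphologies
#'
#' Canonical order used throughout the package: class ids 0..5 map to these
#' names (cell cluster, debris, unattached cell, attached cell, dynamically
#' blebbing cell, apoptotically blebbing cell).
#'
#' @return Character vector of length 6.
#' @export
hesc_class_names <- function() {
  c("cell_cluster", "debris", "unattached_cell",
    "attached_cell", "dynamic_blebbing", "apoptotic_blebbing")
}

#' Labeled and unlabeled image collections
#'
#' A `labeled_dataset` pairs an ordered list of [gray_image] objects with
#' integer class labels in `0..(K-1)`; an `unlabeled_dataset` holds images
#' only.
#'
#' @param images List of [gray_image] objects (or plain matrices, taken as
#'   raw-domain).
#' @param labels Integer vector, same length as `images`, values in
#'   `0..(length(class_names)-1)`.
#' @param class_names Character vector naming the classes (default the six
#'   hESC classes).
#' @return A `labeled_dataset` or `unlabeled_dataset` object.
#' @examples
#' img <- gray_image(matrix(100, 16, 16), "raw")
#' ds <- labeled_dataset(list(img, img), c(0L, 3L))
#' length(ds$images)
#' @export
labeled_dataset <- function(images, labels, class_names = hesc_class_names()) {
  images <- lapply(images, as_gray_image)
  labels <- as.integer(labels)
  if (length(images) != length(labels))
    stopf("images and labels differ in length (%d vs %d)",
          length(images), length(labels))
  k <- length(class_names)
  if (length(labels) && (min(labels) < 0L || max(labels) >= k))
    stopf("labels must lie in 0..%d", k - 1L)
  structure(list(images = images, labels = labels, class_names = class_names),
            class = "labeled_dataset")
}

#' @rdname labeled_dataset
#' @export
unlabeled_dataset <- function(images) {
  structure(list(images = lapply(images, as_gray_image)),
            class = "unlabeled_dataset")
}

as_gray_image <- function(x) {
  if (inherits(x, "gray_image")) return(x)
  gray_image(x, "raw")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, nbins = length(x$class_names))
  cat(sprintf("<labeled_dataset: %d images, %d classes>\n",
              length(x$images), length(x$class_names)))
  cat(paste(sprintf("  %s: %d", x$class_names, tab), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.unlabeled_dataset <- function(x, ...) {
  cat(sprintf("<unlabeled_dataset: %d images>\n", length(x$images)))
  invisible(x)
}

#' Read and write grayscale images
#'
#' `read_gray_image()` reads a PNG or TIFF (or JPEG when \pkg{EBImage} is
#' installed) as a raw-domain \[0, 255\] [gray_image]; multi-channel files are
#' reduced to their first channel.  `write_gray_image()` writes a raw-domain
#' image as an 8-bit PNG.
#'
#' @param path File path.
#' @return `read_gray_image()`: a [gray_image]; `write_gray_image()`: the
#'   path, invisibly.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stopf("JPEG input requires the EBImage package")
      t(as.matrix(EBImage::imageData(
        EBImage::channel(EBImage::readImage(path), "gray"))))
    },
    stopf("unsupported image format: .%s", ext)
  )
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  gray_image(px * 255, "raw")
}

#' @rdname read_gray_image
#' @param image A raw-domain [gray_image].
#' @export
write_gray_image <- function(image, path) {
  image <- as_gray_image(image)
  if (image_domain(image) != "raw")
    stopf("write_gray_image() expects a raw-domain image")
  px <- pmin(pmax(unclass(image) / 255, 0), 1)
  attributes(px) <- list(dim = dim(px))
  png::writePNG(px, target = path)
  invisible(path)
}

#' Load image pools from directory trees
#'
#' `load_labeled_images()` reads a directory-per-class tree (one
#' subdirectory per class, holding PNG/TIFF/JPEG files); subdirectory names
#' give the class names unless `class_names` fixes the order.
#' `load_unlabeled_images()` reads a flat directory of images.
#'
#' @param root Directory with one subdirectory per class.
#' @param class_names Optional class name order; defaults to the six hESC
#'   names when the subdirectories match them, otherwise sorted names.
#' @return A [labeled_dataset] / `unlabeled_dataset`.
#' @export
load_labeled_images <- function(root, class_names = NULL) {
  dirs <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  if (!length(dirs)) stopf("no class subdirectories under %s", root)
  if (is.null(class_names)) {
    class_names <- if (setequal(dirs, hesc_class_names())) hesc_class_names()
                   else sort(dirs)
  }
  missing <- setdiff(class_names, dirs)
  if (length(missing))
    stopf("missing class directories: %s", paste(missing, collapse = ", "))
  images <- list(); labels <- integer(0)
  for (ci in seq_along(class_names)) {
    files <- sort(list.files(file.path(root, class_names[ci]),
                             pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                             ignore.case = TRUE, full.names = TRUE))
    images <- c(images, lapply(files, read_gray_image))
    labels <- c(labels, rep.int(ci - 1L, length(files)))
  }
  labeled_dataset(images, labels, class_names)
}

#' @rdname load_labeled_images
#' @param dir Flat directory of image files.
#' @export
load_unlabeled_images <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                           ignore.case = TRUE, full.names = TRUE))
  unlabeled_dataset(lapply(files, read_gray_image))
}

#' Write a simulated dataset as a PNG tree
#'
#' Writes `root/labeled/<class_name>/NNNN.png`, `root/unlabeled/NNNN.png`
#' and a `manifest.csv` (filename, class_id, seed) as produced by
#' [generate_dataset()].
#'
#' @param labeled A [labeled_dataset].
#' @param unlabeled An `unlabeled_dataset`.
#' @param root Output directory (created if needed).
#' @param seed Seed recorded in the manifest (informational).
#' @return `root`, invisibly.
#' @export
write_image_dataset <- function(labeled, unlabeled, root, seed = NA_integer_) {
  manifest <- data.frame(filename = character(0), class_id = integer(0),
                         seed = integer(0))
  for (ci in seq_along(labeled$class_names)) {
    d <- file.path(root, "labeled", labeled$class_names[ci])
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    idx <- which(labeled$labels == ci - 1L)
    for (j in seq_along(idx)) {
      rel <- file.path("labeled", labeled$class_names[ci],
                       sprintf("%04d.png", j))
      write_gray_image(labeled$images[[idx[j]]], file.path(root, rel))
      manifest <- rbind(manifest, data.frame(filename = rel,
                                             class_id = ci - 1L, seed = seed))
    }
  }
  d <- file.path(root, "unlabeled")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (j in seq_along(unlabeled$images)) {
    rel <- file.path("unlabeled", sprintf("%04d.png", j))
    write_gray_image(unlabeled$images[[j]], file.path(root, rel))
    manifest <- rbind(manifest, data.frame(filename = rel,
                                           class_id = NA_integer_, seed = seed))
  }
  write.csv(manifest, file.path(root, "manifest.csv"), row.names = FALSE)
  invisible(root)
}
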