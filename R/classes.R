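# Pixel class vocabulary and raster containers shared across the pipeline.
#
# Class codes (integer raster values):
#   0 Background, 1 Normal alveoli, 2 Normal airway,
#   3 Grade 1, 4 Grade 2, 5 Grade 3, 6 Grade 4.
# The grading network predicts classes 1..6; Background arises only from
# tissue masking.

#' Pixel class codes
#'
#' Named integer codes for the seven-way pixel vocabulary used throughout the
#' pipeline: background plus the six target classes (two normal lung classes
#' and the four LUAD grades).
#'
#' @format Named integer vector of length 7.
#' @export
CLASS_CODES <- c(
  background     = 0L,
  normal_alveoli = 1L,
  normal_airway  = 2L,
  grade1         = 3L,
  grade2         = 4L,
  grade3         = 5L,
  grade4         = 6L
)

#' @rdname CLASS_CODES
#' @export
GRADE_CODES <- CLASS_CODES[c("grade1", "grade2", "grade3", "grade4")]

#' @rdname CLASS_CODES
#' @export
CLASS_NAMES <- names(CLASS_CODES)

# display palette for indexed label rasters (hex RGB per code 0..6)
CLASS_PALETTE <- c(
  "#FFFFFF", "#C8E6C9", "#4CAF50", "#FFF59D", "#FFB74D", "#E57373", "#8E24AA"
)

#' Reference scan resolution (microns per pixel)
#'
#' Scan resolution of the slides the pipeline is calibrated for
#' (20x magnification, 0.5022 um/pixel).
#' @export
REFERENCE_MPP <- 0.5022

class_name <- function(code) CLASS_NAMES[match(code, CLASS_CODES)]

#' Construct a grade map
#'
#' A grade map is an integer matrix of pixel class codes (see [CLASS_CODES])
#' with a physical resolution attribute. It is the central exchange object
#' between the grading network, tumor analytics, and IHC projection.
#'
#' @param labels integer matrix of class codes in 0..6.
#' @param microns_per_pixel physical resolution, um/pixel.
#' @return An object of class `grade_map` (integer matrix with attributes).
#' @export
grade_map <- function(labels, microns_per_pixel = REFERENCE_MPP) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L | labels > 6L, na.rm = TRUE))
    stop("grade map codes must lie in 0..6")
  structure(labels,
            microns_per_pixel = microns_per_pixel,
            class = c("grade_map", "matrix", "array"))
}

#' @export
print.grade_map <- function(x, ...) {
  tab <- table(factor(x, levels = CLASS_CODES, labels = CLASS_NAMES))
  cat(sprintf("<grade_map> %d x %d px @ %.4f um/px\n",
              nrow(x), ncol(x), attr(x, "microns_per_pixel")))
  print(tab)
  invisible(x)
}

mpp_of <- function(x) {
  mpp <- attr(x, "microns_per_pixel")
  if (is.null(mpp)) REFERENCE_MPP else mpp
}

#' Construct a label mask
#'
#' Ground-truth counterpart of a [grade_map()]: a per-pixel class raster paired
#' with an annotated slide.
#'
#' @inheritParams grade_map
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, microns_per_pixel = REFERENCE_MPP) {
  gm <- grade_map(labels, microns_per_pixel)
  class(gm) <- c("label_mask", class(gm))
  gm
}

# ---- image IO --------------------------------------------------------------

#' Read / write 8-bit RGB images
#'
#' Thin wrappers over the `png` and `tiff` packages. Images are represented in
#' R as numeric arrays (H, W, 3) with values in 0..255.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param image numeric (H, W, 3) array, values 0..255.
#' @return `read_rgb` returns a (H, W, 3) array in 0..255.
#' @export
read_rgb <- function(path) {
  img <- switch(tolower(tools::file_ext(path)),
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", path)
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' @rdname read_rgb
#' @export
write_rgb <- function(image, path) {
  img <- pmin(pmax(image / 255, 0), 1)
  switch(tolower(tools::file_ext(path)),
    png  = png::writePNG(img, path),
    tif  = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported image format: ", path)
  )
  invisible(path)
}

#' Read / write indexed label rasters
#'
#' Label rasters are stored as single-channel 8-bit PNG/TIFF whose pixel value
#' is the class code (0..6). A JSON sidecar carries the resolution.
#'
#' @param labels integer matrix of class codes (a [grade_map()] or
#'   [label_mask()] works).
#' @param path image path; the sidecar is `<path>.json`.
#' @return `read_label_raster` returns a [grade_map()].
#' @export
write_label_raster <- function(labels, path) {
  img <- matrix(as.numeric(labels) / 255, nrow(labels), ncol(labels))
  switch(tolower(tools::file_ext(path)),
    png  = png::writePNG(img, path),
    tif  = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported image format: ", path)
  )
  jsonlite::write_json(
    list(microns_per_pixel = mpp_of(labels), codes = as.list(CLASS_CODES)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_label_raster
#' @export
read_label_raster <- function(path) {
  img <- switch(tolower(tools::file_ext(path)),
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", path)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1]
  mpp <- REFERENCE_MPP
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    mpp <- jsonlite::read_json(sidecar)$microns_per_pixel
  grade_map(round(img * 255), microns_per_pixel = mpp)
}

# internal helpers ------------------------------------------------------------

stopifnot_rgb <- function(image) {
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("expected an RGB raster with dim (H, W, 3)")
  invisible(d)
}

rgb_to_gray <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}
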