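#' Read and write depth images
#'
#' Depth frames are single-channel images whose pixel value is range in
#' millimetres; 0 marks "no measurement". On disk they are stored as 16-bit
#' grayscale TIFF (value = mm, up to 65535). 16-bit grayscale PNG files
#' (the other common convention for Kinect-style sensors) are read through
#' the same function. Non-finite or negative values are mapped to the
#' invalid marker 0 at load time.
#'
#' @param path File to read or write (`.tif`/`.tiff` to write; `.png` also
#'   accepted when reading).
#' @param depth Numeric matrix of depth in mm; values are rounded to
#'   integer mm on write and clipped to \[0, 65535\].
#' @return `read_depth()` returns a numeric matrix in mm (rows = image
#'   rows); `write_depth()` returns `path` invisibly.
#' @export
read_depth <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  depth <- round(img * 65535)
  depth[!is.finite(depth) | depth < 0] <- 0
  depth
}

#' @rdname read_depth
#' @export
write_depth <- function(depth, path) {
  stopifnot(is.matrix(depth))
  d <- round(depth)
  d[!is.finite(d) | d < 0] <- 0
  d[d > 65535] <- 65535
  tiff::writeTIFF(d / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read and write 3-class label maps
#'
#' Label maps are 8-bit grayscale PNG images with pixel codes 0
#' (background), 1 (fruit) and 2 (branch), matching the frame dimensions
#' of the depth image.
#'
#' @param path PNG file to read or write.
#' @param labels Integer matrix with values in `{0, 1, 2}`.
#' @return `read_labels()` returns an integer matrix; `write_labels()`
#'   returns `path` invisibly.
#' @export
read_labels <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  lab <- round(img * 255)
  if (!all(lab %in% 0:2)) {
    abort("label map contains codes outside {0, 1, 2}",
          class = "guavapose_parameter_error")
  }
  storage.mode(lab) <- "integer"
  lab
}

#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  stopifnot(is.matrix(labels))
  if (!all(labels %in% 0:2)) {
    abort("label map must contain only codes {0, 1, 2}",
          class = "guavapose_parameter_error")
  }
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' Read and write RGB images
#'
#' Thin wrappers over [png::readPNG()]/[png::writePNG()] returning an
#' `rows x cols x 3` array with channels in `[0, 1]`.
#'
#' @param path PNG file.
#' @param rgb `rows x cols x 3` numeric array in `[0, 1]`.
#' @export
read_rgb <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3]
  img
}

#' @rdname read_rgb
#' @export
write_rgb <- function(rgb, path) {
  stopifnot(length(dim(rgb)) == 3)
  png::writePNG(pmin(pmax(rgb, 0), 1), path)
  invisible(path)
}

#' Export a labelled point cloud as ASCII PLY
#'
#' Writes one vertex per point with properties `x y z label`, readable by
#' standard point-cloud viewers.
#'
#' @param points Data frame with `x`, `y`, `z` columns (mm) and optionally
#'   a `label` column (defaults to 0).
#' @param path Output `.ply` file.
#' @return `path`, invisibly.
#' @export
write_ply <- function(points, path) {
  xyz <- as_xyz(points)
  label <- if (is.data.frame(points) && "label" %in% names(points)) {
    as.integer(points$label)
  } else {
    integer(nrow(xyz))
  }
  header <- c(
    "ply", "format ascii 1.0",
    sprintf("element vertex %d", nrow(xyz)),
    "property float x", "property float y", "property float z",
    "property uchar label", "end_header")
  body <- sprintf("%.6g %.6g %.6g %d", xyz[, 1], xyz[, 2], xyz[, 3], label)
  writeLines(c(header, body), path)
  invisible(path)
}
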