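#' Back-project a depth image to a labelled 3D point cloud
#'
#' Converts every selected pixel with positive depth to camera-frame
#' millimetre coordinates with the pinhole model
#' \deqn{x = z (u - U_x) / f_x, \quad y = z (v - U_y) / f_y, \quad z = I_{depth}(u, v),}
#' where `u` is the 0-based column and `v` the 0-based row of the pixel.
#' Pixels with depth 0 (the invalid marker) are never converted. Points are
#' emitted in row-major order (by row `v`, then column `u`), so output
#' ordering is deterministic.
#'
#' @param depth Numeric matrix of depth in mm (0 = invalid).
#' @param intrinsics A [camera_intrinsics()] object.
#' @param labels Optional integer matrix of per-pixel class codes
#'   (0 background / 1 fruit / 2 branch) with the same dimensions as
#'   `depth`; copied onto the points.
#' @param mask Optional logical matrix selecting the pixels to convert
#'   (same dimensions as `depth`). Default: all pixels.
#' @return A tibble with one row per converted pixel: `u`, `v` (0-based
#'   pixel coordinates), `x`, `y`, `z` (mm) and `label` (0 when no label
#'   map was given).
#' @examples
#' cam <- camera_intrinsics(500, 500, ux = 2, uy = 1)
#' d <- matrix(0, 3, 5); d[2, 3] <- 1000
#' backproject(d, cam) # principal ray: x = y = 0
#' @export
backproject <- function(depth, intrinsics, labels = NULL, mask = NULL) {
  intrinsics <- as_camera_intrinsics(intrinsics)
  stopifnot(is.matrix(depth))
  if (!is.null(labels) && !all(dim(labels) == dim(depth))) {
    abort("`labels` dimensions must match `depth`",
          class = "guavapose_parameter_error")
  }
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(depth))) {
      abort("`mask` dimensions must match `depth`",
            class = "guavapose_parameter_error")
    }
    sel <- mask & depth > 0
  } else {
    sel <- depth > 0
  }
  idx <- which(sel)                       # column-major linear indices
  row <- (idx - 1L) %% nrow(depth) + 1L   # 1-based image row
  col <- (idx - 1L) %/% nrow(depth) + 1L  # 1-based image column
  ord <- order(row, col)                  # row-major emission order
  row <- row[ord]; col <- col[ord]; idx <- idx[ord]

  z <- depth[idx]
  if (length(z) && any(z < intrinsics$min_range_mm)) {
    warn(sprintf("%d pixel(s) closer than the minimum trusted range (%g mm)",
                 sum(z < intrinsics$min_range_mm), intrinsics$min_range_mm))
  }
  u <- col - 1
  v <- row - 1
  lab <- if (is.null(labels)) integer(length(idx)) else as.integer(labels[idx])
  tibble(
    u = u, v = v,
    x = z * (u - intrinsics$ux) / intrinsics$fx,
    y = z * (v - intrinsics$uy) / intrinsics$fy,
    z = z,
    label = lab
  )
}

#' Project 3D points to continuous pixel coordinates
#'
#' Inverse of [backproject()]: `u = fx * x / z + ux`, `v = fy * y / z + uy`.
#' Projection of a back-projected pixel returns the pixel's (0-based)
#' coordinates exactly, up to floating tolerance.
#'
#' @param points Data frame with `x`, `y`, `z` columns (mm), an n x 3
#'   matrix, or a length-3 vector. All `z` must be positive.
#' @param intrinsics A [camera_intrinsics()] object.
#' @return A tibble with columns `u`, `v` (continuous, 0-based) and `z`.
#' @export
project <- function(points, intrinsics) {
  intrinsics <- as_camera_intrinsics(intrinsics)
  xyz <- as_xyz(points)
  if (any(xyz[, 3] <= 0)) {
    abort("all points must have z > 0 to project",
          class = "guavapose_domain_error")
  }
  tibble(
    u = intrinsics$fx * xyz[, 1] / xyz[, 3] + intrinsics$ux,
    v = intrinsics$fy * xyz[, 2] / xyz[, 3] + intrinsics$uy,
    z = xyz[, 3]
  )
}
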