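#' Pinhole camera intrinsics
#'
#' Bundle the pinhole parameters that map depth pixels to 3D millimetre
#' coordinates: focal lengths `fx`, `fy` (pixels) and the principal point
#' `(ux, uy)` (pixel coordinates, 0-based, `u` = column and `v` = row).
#' `min_range_mm` records the closest distance at which the sensor returns
#' trustworthy depth (550 mm for a Kinect V2 pointed at a tree canopy);
#' depths below it are kept but flagged with a warning at back-projection.
#'
#' @param fx,fy Focal lengths in pixels; must be positive.
#' @param ux,uy Principal point (column, row) in pixels; must be finite.
#' @param min_range_mm Minimum trusted sensor range in millimetres.
#' @return An object of class `camera_intrinsics`.
#' @examples
#' cam <- camera_intrinsics(fx = 365, fy = 365, ux = 256, uy = 212)
#' cam
#' @export
camera_intrinsics <- function(fx, fy, ux, uy, min_range_mm = 550) {
  if (!is.numeric(fx) || !is.numeric(fy) || fx <= 0 || fy <= 0) {
    abort("focal lengths fx, fy must be positive numbers",
          class = "guavapose_parameter_error")
  }
  if (!is.finite(ux) || !is.finite(uy)) {
    abort("principal point ux, uy must be finite",
          class = "guavapose_parameter_error")
  }
  structure(
    list(fx = as.numeric(fx), fy = as.numeric(fy),
         ux = as.numeric(ux), uy = as.numeric(uy),
         min_range_mm = as.numeric(min_range_mm)),
    class = "camera_intrinsics"
  )
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf(
    "<camera_intrinsics> fx=%.6g fy=%.6g ux=%.6g uy=%.6g min_range=%.6g mm\n",
    x$fx, x$fy, x$ux, x$uy, x$min_range_mm))
  invisible(x)
}

as_camera_intrinsics <- function(x) {
  if (inherits(x, "camera_intrinsics")) return(x)
  if (is.list(x) && all(c("fx", "fy", "ux", "uy") %in% names(x))) {
    return(camera_intrinsics(x$fx, x$fy, x$ux, x$uy,
                             x$min_range_mm %||% 550))
  }
  abort("expected a `camera_intrinsics` object or a list with fx, fy, ux, uy",
        class = "guavapose_parameter_error")
}

#' Read or write camera intrinsics
#'
#' Intrinsics are serialised as a flat YAML or JSON block with keys
#' `fx, fy, ux, uy, min_range_mm`; the format is chosen from the file
#' extension (`.yaml`/`.yml` vs `.json`).
#'
#' @param path File to read or write.
#' @param intrinsics A [camera_intrinsics()] object.
#' @return `read_intrinsics()` returns a `camera_intrinsics` object;
#'   `write_intrinsics()` returns `path` invisibly.
#' @export
read_intrinsics <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_camera_intrinsics(vals)
}

#' @rdname read_intrinsics
#' @export
write_intrinsics <- function(intrinsics, path) {
  intrinsics <- as_camera_intrinsics(intrinsics)
  vals <- unclass(intrinsics)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}
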