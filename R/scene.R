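#' Specify a synthetic orchard scene
#'
#' Describes a scene of cylindrical branches with spherical fruits
#' attached perpendicular to them, in camera coordinates (mm, z along the
#' optical axis). Each fruit hangs off its mother branch along an offset
#' direction perpendicular to the branch axis; its centre sits at
#' `attachment + (branch_radius + pedicel + fruit_radius) * offset`, so
#' the true centre, mother branch, nearest branch point (the attachment
#' point on the axis) and pose (the offset direction) are all known by
#' construction — which is what makes the generator usable as ground
#' truth for every pipeline stage.
#'
#' @param branches Data frame with one row per branch: anchor `x, y, z`
#'   (mm), axis `ax, ay, az` (normalised internally), `length` (mm),
#'   `radius` (mm).
#' @param fruits Data frame with one row per fruit: `branch` (1-based
#'   mother index), `attach` (mm along the axis from the anchor), offset
#'   direction `ox, oy, oz` (must be perpendicular to the mother axis
#'   within 1e-9 after normalisation), `pedicel` (mm) and `radius` (mm).
#'   May be empty or `NULL`.
#' @param camera A [camera_intrinsics()] object.
#' @param image_size `c(rows, cols)` of the rendered frame (default the
#'   424 x 512 depth-frame convention).
#' @param noise_sigma Std. dev. of per-pixel Gaussian depth noise in mm
#'   (default 0).
#' @param max_incidence_deg Sensor validity angle: surface hits seen at
#'   more than this angle from their normal return no depth. 50 (default)
#'   emulates a conservative time-of-flight sensor that drops unreliable
#'   grazing returns; 90 is an ideal camera that keeps silhouette points.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(branches, fruits = NULL,
                       camera = default_camera(),
                       image_size = c(424, 512),
                       noise_sigma = 0,
                       max_incidence_deg = 50) {
  stopifnot(is.data.frame(branches))
  camera <- as_camera_intrinsics(camera)
  if (is.null(fruits)) {
    fruits <- tibble(branch = integer(), attach = numeric(),
                     ox = numeric(), oy = numeric(), oz = numeric(),
                     pedicel = numeric(), radius = numeric())
  }
  branches <- as_tibble(branches)
  fruits <- as_tibble(fruits)
  if (any(branches$length <= 0) || any(branches$radius <= 0) ||
      any(fruits$radius <= 0)) {
    abort("branch lengths and all radii must be positive",
          class = "guavapose_parameter_error")
  }
  for (i in seq_len(nrow(branches))) {
    ax <- unitize(c(branches$ax[i], branches$ay[i], branches$az[i]), "axis")
    branches$ax[i] <- ax[1]; branches$ay[i] <- ax[2]; branches$az[i] <- ax[3]
  }
  for (i in seq_len(nrow(fruits))) {
    j <- fruits$branch[i]
    if (is.na(j) || j < 1 || j > nrow(branches)) {
      abort("fruit refers to a non-existent branch",
            class = "guavapose_parameter_error")
    }
    off <- unitize(c(fruits$ox[i], fruits$oy[i], fruits$oz[i]), "offset")
    axis <- c(branches$ax[j], branches$ay[j], branches$az[j])
    if (abs(sum(off * axis)) > 1e-9) {
      abort("fruit offset direction must be perpendicular to its mother axis",
            class = "guavapose_parameter_error")
    }
    fruits$ox[i] <- off[1]; fruits$oy[i] <- off[2]; fruits$oz[i] <- off[3]
  }
  structure(list(branches = branches, fruits = fruits, camera = camera,
                 image_size = as.integer(image_size),
                 noise_sigma = as.numeric(noise_sigma),
                 max_incidence_deg = as.numeric(max_incidence_deg)),
            class = "scene_spec")
}

#' Default simulator camera
#'
#' Kinect-V2-like depth intrinsics for the 424 x 512 frame convention:
#' focal lengths 365 px and principal point at (256, 212).
#' @return A [camera_intrinsics()] object.
#' @export
default_camera <- function() camera_intrinsics(365, 365, 256, 212)

#' Resolve scene geometry and ground truth
#'
#' Expands a [scene_spec()] into per-object geometry plus the truth
#' records used by the tests: for each fruit its centre, pose vector
#' (= offset direction), attachment point and mother branch; for each
#' branch its axis anchor, unit direction and extent.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `scene` with elements `spec`, `truth_fruits`
#'   (tibble: `fruit_id`, `branch`, `cx..cz`, `qx..qz`, `nx..nz`,
#'   `radius`) and `truth_branches` (tibble: `branch_id`, `px..pz`,
#'   `tx..tz`, `s_min`, `s_max`, `radius`).
#' @export
build_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  br <- spec$branches
  truth_branches <- tibble(
    branch_id = seq_len(nrow(br)),
    px = br$x, py = br$y, pz = br$z,
    tx = br$ax, ty = br$ay, tz = br$az,
    s_min = 0, s_max = br$length, radius = br$radius)
  fr <- spec$fruits
  rows <- purrr::map(seq_len(nrow(fr)), function(i) {
    j <- fr$branch[i]
    anchor <- c(br$x[j], br$y[j], br$z[j])
    axis <- c(br$ax[j], br$ay[j], br$az[j])
    off <- c(fr$ox[i], fr$oy[i], fr$oz[i])
    attach_pt <- anchor + fr$attach[i] * axis
    ctr <- attach_pt + (br$radius[j] + fr$pedicel[i] + fr$radius[i]) * off
    tibble(fruit_id = i, branch = j,
           cx = ctr[1], cy = ctr[2], cz = ctr[3],
           qx = off[1], qy = off[2], qz = off[3],
           nx = attach_pt[1], ny = attach_pt[2], nz = attach_pt[3],
           radius = fr$radius[i])
  })
  truth_fruits <- if (length(rows) == 0) {
    tibble(fruit_id = integer(), branch = integer(),
           cx = numeric(), cy = numeric(), cz = numeric(),
           qx = numeric(), qy = numeric(), qz = numeric(),
           nx = numeric(), ny = numeric(), nz = numeric(),
           radius = numeric())
  } else {
    dplyr::bind_rows(rows)
  }
  min_z <- spec$camera$min_range_mm
  zs <- c(truth_fruits$cz, br$z)
  if (length(zs) && any(zs <= min_z)) {
    warn("some scene objects are closer than the camera's minimum trusted range")
  }
  structure(list(spec = spec, truth_fruits = truth_fruits,
                 truth_branches = truth_branches),
            class = "scene")
}
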