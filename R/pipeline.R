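#' Pipeline configuration
#'
#' Bundles every tunable of the detection/pose pipeline. `strict = TRUE`
#' pins the exact published operating point — 4 mm clustering radius,
#' 15 mm line inlier threshold, 4000 candidate draws, acceptance strictly
#' above 40 inliers, and no least-squares line refinement (the raw
#' two-point model is kept).
#'
#' @param intrinsics A [camera_intrinsics()] object.
#' @param cluster A [cluster_params()] object.
#' @param lines A [line_params()] object.
#' @param center_method `"sphere_fit"` or `"bounding_box"`.
#' @param match_tol Centre-matching tolerance for evaluation, mm.
#' @param clamp_to_extent Use finite-segment distances for mother-branch
#'   assignment (default `FALSE`: the infinite line).
#' @param strict Pin the published parameter set (overrides `cluster`
#'   distance threshold and `lines`).
#' @param seed Integer seed driving the RANSAC draws.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(intrinsics = default_camera(),
                            cluster = cluster_params(),
                            lines = line_params(),
                            center_method = c("sphere_fit", "bounding_box"),
                            match_tol = 30,
                            clamp_to_extent = FALSE,
                            strict = FALSE,
                            seed = 1L) {
  center_method <- match.arg(center_method)
  if (strict) {
    cluster <- cluster_params(4, cluster$min_cluster_size)
    lines <- line_params(15, 4000, 40, refine = FALSE)
  }
  structure(list(intrinsics = as_camera_intrinsics(intrinsics),
                 cluster = cluster, lines = lines,
                 center_method = center_method,
                 match_tol = as.numeric(match_tol),
                 clamp_to_extent = isTRUE(clamp_to_extent),
                 strict = isTRUE(strict),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Save or load a pipeline configuration as YAML
#'
#' The YAML round-trip is loss-free: `read_pipeline_config(write_pipeline_config(cfg))`
#' reproduces `cfg`.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(list(
    intrinsics = unclass(config$intrinsics),
    cluster = unclass(config$cluster),
    lines = unclass(config$lines),
    center_method = config$center_method,
    match_tol = config$match_tol,
    clamp_to_extent = config$clamp_to_extent,
    strict = config$strict,
    seed = config$seed), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  v <- yaml::read_yaml(path)
  pipeline_config(
    intrinsics = as_camera_intrinsics(v$intrinsics),
    cluster = cluster_params(v$cluster$distance_threshold,
                             v$cluster$min_cluster_size),
    lines = line_params(v$lines$inlier_threshold, v$lines$iterations,
                        v$lines$min_inliers, v$lines$refine),
    center_method = v$center_method,
    match_tol = v$match_tol,
    clamp_to_extent = v$clamp_to_extent,
    strict = v$strict,
    seed = v$seed)
}

#' Run the full detection and pose pipeline on one frame
#'
#' Orchestrates the four stages on an aligned RGB-D frame with a 3-class
#' segmentation: (i) back-project labelled depth pixels to a point cloud,
#' (ii) cluster the fruit points into individual fruits and estimate
#' centres, (iii) thin the branch mask to a skeleton and reconstruct 3D
#' line segments, (iv) assign each fruit its mother branch and compute
#' its perpendicular approach pose. Any empty intermediate result
#' propagates gracefully (no fruit, no branches, and hence no poses — not
#' an error). Deterministic for a fixed `config$seed`.
#'
#' @param depth Depth matrix in mm (0 = invalid).
#' @param labels Integer matrix of codes `{0, 1, 2}`, same dimensions; or
#'   an RGB array, in which case [segment_baseline()] is applied first.
#' @param config A [pipeline_config()].
#' @return A list of class `guava_pipeline`: `cloud`, `detections`,
#'   `segments`, `poses`, `unposed`, `report` (per-stage counts) and
#'   `config`. [tidy()] returns the pose table, [glance()] the report.
#' @export
run_pipeline <- function(depth, labels, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.array(labels) && length(dim(labels)) == 3) {
    labels <- segment_baseline(labels)
  }
  if (!all(dim(labels) == dim(depth))) {
    abort("`labels` and `depth` dimensions differ",
          class = "guavapose_parameter_error")
  }
  cloud <- backproject(depth, config$intrinsics, labels = labels,
                       mask = labels > 0L)
  detections <- detect_fruits(cloud, config$cluster, config$center_method)
  segments <- reconstruct_branches(labels, depth, config$intrinsics,
                                   config$lines, seed = config$seed)
  poses <- estimate_all_poses(detections, segments,
                              clamp = config$clamp_to_extent)
  report <- tibble(
    n_points = nrow(cloud),
    n_fruit_points = sum(cloud$label == 1L),
    n_branch_points = sum(cloud$label == 2L),
    n_detections = nrow(detections),
    n_segments = nrow(segments),
    n_poses = sum(poses$posed),
    n_unposed = sum(!poses$posed),
    seed = config$seed)
  structure(list(cloud = cloud, detections = detections, segments = segments,
                 poses = poses, unposed = attr(poses, "unposed"),
                 report = report, config = config),
            class = "guava_pipeline")
}

#' @export
print.guava_pipeline <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<guava_pipeline> %d labelled points -> %d fruits, ",
                     "%d branch segments, %d poses (%d unposed)\n"),
              r$n_points, r$n_detections, r$n_segments, r$n_poses,
              r$n_unposed))
  invisible(x)
}

#' @method tidy guava_pipeline
#' @export
tidy.guava_pipeline <- function(x, ...) x$poses

#' @method glance guava_pipeline
#' @export
glance.guava_pipeline <- function(x, ...) x$report

#' Export pipeline results as JSON
#'
#' Writes `detections.json`, `segments.json`, `poses.json` and
#' `report.json` (stage counts and parameters) into `dir`. Output is
#' byte-identical across reruns with the same inputs and seed.
#'
#' @param result A `guava_pipeline` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(result, dir) {
  stopifnot(inherits(result, "guava_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  det <- result$detections
  det$members <- NULL
  seg <- result$segments
  seg$inliers <- NULL
  jsonlite::write_json(det, file.path(dir, "detections.json"),
                       digits = NA, dataframe = "rows")
  jsonlite::write_json(seg, file.path(dir, "segments.json"),
                       digits = NA, dataframe = "rows")
  jsonlite::write_json(result$poses, file.path(dir, "poses.json"),
                       digits = NA, dataframe = "rows")
  jsonlite::write_json(result$report, file.path(dir, "report.json"),
                       digits = NA, dataframe = "rows")
  invisible(dir)
}
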