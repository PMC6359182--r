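#' Perpendicular distance from points to an infinite 3D line
#'
#' For a line through `p` with unit direction `t`, returns
#' \eqn{\|(c - p) - ((c - p) \cdot t)\, t\|} for each point `c` — the norm
#' of the component of `c - p` perpendicular to the line. This is the
#' residual used both to collect line inliers and to pick a fruit's mother
#' branch.
#'
#' @param points Data frame with `x`, `y`, `z`, an n x 3 matrix, or a
#'   length-3 vector.
#' @param p Length-3 anchor point on the line (mm).
#' @param t Length-3 direction; normalised internally (with a warning if
#'   its norm is not 1 within 1e-9).
#' @return Numeric vector of distances in mm.
#' @export
point_line_distance <- function(points, p, t) {
  xyz <- as_xyz(points)
  nt <- sqrt(sum(t^2))
  if (abs(nt - 1) > 1e-9) {
    warn("`t` is not unit length; normalising")
    t <- t / nt
  }
  w <- sweep(xyz, 2, p)
  proj <- as.vector(w %*% t)
  d2 <- pmax(rowSums(w^2) - proj^2, 0)
  sqrt(d2)
}

#' Line-detection parameters
#'
#' Controls the sequential RANSAC detector: `inlier_threshold` is the
#' maximum perpendicular distance (mm) for a skeleton point to support a
#' candidate line (15 mm absorbs skeleton jitter and branch curvature);
#' `iterations` is the number of random two-point candidates drawn per
#' accepted-segment round (4000); a candidate becomes a segment only when
#' its inlier count strictly exceeds `min_inliers` (40), which stops the
#' detector fragmenting noise into spurious branches. `refine` switches
#' the post-acceptance least-squares re-estimate of the line (principal
#' axis of the inliers); turning it off keeps the raw two-point model.
#'
#' @param inlier_threshold Positive distance in mm (default 15).
#' @param iterations Candidate draws per round (default 4000).
#' @param min_inliers Acceptance threshold on inlier count, strict
#'   (default 40).
#' @param refine Re-fit accepted lines by least squares (default `TRUE`).
#' @return A list of class `line_params`.
#' @export
line_params <- function(inlier_threshold = 15, iterations = 4000,
                        min_inliers = 40, refine = TRUE) {
  if (inlier_threshold <= 0 || iterations <= 0 || min_inliers <= 0) {
    abort("line-detection parameters must all be positive",
          class = "guavapose_parameter_error")
  }
  structure(list(inlier_threshold = as.numeric(inlier_threshold),
                 iterations = as.integer(iterations),
                 min_inliers = as.integer(min_inliers),
                 refine = isTRUE(refine)),
            class = "line_params")
}

#' Detect multiple 3D line segments by sequential RANSAC
#'
#' Greedy multi-model detection on a branch point cloud. Each round draws
#' `iterations` random two-point candidates `(p1, t1)` with
#' `t1 = (p1 - p2) / |p1 - p2|` (coincident draws are redrawn), scores
#' each by its inlier count within `inlier_threshold` of the infinite
#' line, and accepts the consensus-maximising candidate iff its count
#' strictly exceeds `min_inliers`; accepted inliers are removed and the
#' next round starts, otherwise detection stops. Accepted lines are
#' optionally refined by a least-squares fit (centroid + principal axis of
#' the inliers); the segment extent is the min/max of inlier projections
#' along the direction. Directions follow a fixed sign convention
#' (non-negative z, ties towards non-negative y then x) and results are
#' deterministic given `seed`.
#'
#' Because candidates are full 3D lines, two branches that are collinear
#' in the 2D image but lie at different depths are recovered as two
#' distinct segments.
#'
#' @param points Data frame with `x`, `y`, `z` (mm) or n x 3 matrix; may
#'   be empty.
#' @param params A [line_params()] object.
#' @param seed Optional integer seed.
#' @return A tibble with one row per segment: `segment_id`, anchor
#'   `px, py, pz`, unit direction `tx, ty, tz`, `s_min`, `s_max` (extent
#'   of inlier projections along the direction, relative to the anchor),
#'   `n_inliers`, and `inliers` (list-column of row indices into
#'   `points`). Inlier sets of different segments are disjoint.
#' @export
detect_line_segments <- function(points, params = line_params(), seed = NULL) {
  stopifnot(inherits(params, "line_params"))
  xyz <- if (is.null(points) || (is.data.frame(points) && nrow(points) == 0)) {
    matrix(numeric(0), 0, 3)
  } else {
    as_xyz(points)
  }
  empty <- tibble(segment_id = integer(),
                  px = numeric(), py = numeric(), pz = numeric(),
                  tx = numeric(), ty = numeric(), tz = numeric(),
                  s_min = numeric(), s_max = numeric(),
                  n_inliers = integer(), inliers = list())
  if (nrow(xyz) < 2) return(empty)

  with_seed(seed, {
    remaining <- seq_len(nrow(xyz))
    segs <- list()
    repeat {
      m <- length(remaining)
      if (m < 2) break
      pts <- xyz[remaining, , drop = FALSE]
      best <- ransac_line_round(pts, params)
      if (is.null(best) || best$count <= params$min_inliers) break
      inl_local <- best$inliers
      inl_pts <- pts[inl_local, , drop = FALSE]
      if (params$refine) {
        p <- colMeans(inl_pts)
        sv <- svd(sweep(inl_pts, 2, p))
        t <- canonical_direction(sv$v[, 1])
      } else {
        p <- best$p
        t <- canonical_direction(best$t)
      }
      s <- as.vector(sweep(inl_pts, 2, p) %*% t)
      segs[[length(segs) + 1L]] <- tibble(
        segment_id = length(segs) + 1L,
        px = p[1], py = p[2], pz = p[3],
        tx = t[1], ty = t[2], tz = t[3],
        s_min = min(s), s_max = max(s),
        n_inliers = length(inl_local),
        inliers = list(remaining[inl_local]))
      remaining <- remaining[-inl_local]
    }
    if (length(segs) == 0) empty else dplyr::bind_rows(segs)
  })
}

# One RANSAC round: draw `iterations` two-point candidates from `pts` and
# return the consensus-maximising line (local inlier indices).
ransac_line_round <- function(pts, params) {
  m <- nrow(pts)
  thr2 <- params$inlier_threshold^2
  norms2 <- rowSums(pts^2)
  best <- NULL
  best_count <- -1L
  for (k in seq_len(params$iterations)) {
    tries <- 0L
    repeat {
      ij <- sample.int(m, 2)
      delta <- pts[ij[1], ] - pts[ij[2], ]
      len <- sqrt(sum(delta^2))
      if (len > 0) break
      tries <- tries + 1L
      if (tries >= 20L) return(best)   # all sampled points coincide
    }
    p <- pts[ij[1], ]
    t <- delta / len
    w_proj <- as.vector(pts %*% t) - sum(p * t)
    d2 <- norms2 - 2 * as.vector(pts %*% p) + sum(p^2) - w_proj^2
    count <- sum(d2 <= thr2)
    if (count > best_count) {
      best_count <- count
      best <- list(p = p, t = t, count = count, inliers = which(d2 <= thr2))
    }
  }
  best
}

#' Reconstruct branches from a frame
#'
#' Full branch path: the branch plane of the label map (code 2) is thinned
#' with [skeletonize()], skeleton pixels with valid depth are
#' back-projected to 3D, and [detect_line_segments()] approximates the
#' branch cloud with straight 3D segments. Empty input at any stage yields
#' an empty segment table.
#'
#' @param labels Integer matrix of class codes `{0, 1, 2}`.
#' @param depth Depth matrix in mm (0 = invalid), same dimensions.
#' @param intrinsics A [camera_intrinsics()] object.
#' @param params A [line_params()] object.
#' @param seed Optional integer seed for the RANSAC draws.
#' @return A segment tibble as from [detect_line_segments()] (inlier
#'   indices refer to the skeleton point cloud, returned as attribute
#'   `"skeleton_cloud"`).
#' @export
reconstruct_branches <- function(labels, depth, intrinsics,
                                 params = line_params(), seed = NULL) {
  stopifnot(all(dim(labels) == dim(depth)))
  skel <- skeletonize(labels == 2L)
  cloud <- backproject(depth, intrinsics, mask = skel)
  segs <- detect_line_segments(cloud, params, seed = seed)
  attr(segs, "skeleton_cloud") <- cloud
  segs
}
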