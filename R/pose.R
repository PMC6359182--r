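#' Assign a fruit its mother branch
#'
#' The mother branch of a fruit is the reconstructed segment minimising
#' the perpendicular distance from the fruit centre to the segment's
#' infinite line,
#' \deqn{j = \arg\min_k \|(c - p_k) - ((c - p_k)^T t_k)\, t_k\|.}
#' Ties are broken by the smallest index. Because the infinite line can
#' occasionally select a far-away collinear segment as a false mother
#' branch, `clamp = TRUE` measures the distance to the finite segment
#' (projections clipped to `[s_min, s_max]`) instead.
#'
#' @param center Length-3 fruit centre (mm).
#' @param segments Segment tibble from [detect_line_segments()].
#' @param clamp Use the finite-extent distance instead of the infinite
#'   line (default `FALSE`).
#' @return The 1-based row index of the mother branch in `segments`, or
#'   `NA_integer_` when `segments` is empty (no branch available — the
#'   fruit's pose cannot be estimated).
#' @export
assign_mother_branch <- function(center, segments, clamp = FALSE) {
  if (is.null(segments) || nrow(segments) == 0) return(NA_integer_)
  d <- vapply(seq_len(nrow(segments)), function(k) {
    seg <- segments[k, ]
    p <- c(seg$px, seg$py, seg$pz)
    t <- c(seg$tx, seg$ty, seg$tz)
    if (clamp) {
      s <- sum((center - p) * t)
      s <- min(max(s, seg$s_min), seg$s_max)
      sqrt(sum((center - (p + s * t))^2))
    } else {
      point_line_distance(center, p, t)
    }
  }, numeric(1))
  which.min(d)  # which.min returns the first (smallest-index) minimiser
}

#' Estimate the branch-relative pose of one fruit
#'
#' Given the fruit centre `c` and its mother branch `(p, t)`, the nearest
#' point of the branch line to the centre is
#' \eqn{n = p + ((c - p)^T t)\, t} and the fruit pose is the unit vector
#' \eqn{\tilde q = (c - n) / \|c - n\|} — by construction perpendicular to
#' the branch, so a gripper approaching along \eqn{-\tilde q} does not
#' collide with it. A centre lying on the line (within 1e-6 mm) has no
#' defined pose and raises a `guavapose_degenerate_pose` condition.
#'
#' @param center Length-3 fruit centre (mm).
#' @param segment One-row segment tibble (or list with `px..pz`,
#'   `tx..tz`).
#' @return A list with `nearest_point`, `pose` (unit 3-vector) and
#'   `distance_to_branch` (mm).
#' @export
estimate_pose <- function(center, segment) {
  p <- c(segment$px, segment$py, segment$pz)
  t <- c(segment$tx, segment$ty, segment$tz)
  n <- p + sum((center - p) * t) * t
  delta <- center - n
  dist <- sqrt(sum(delta^2))
  if (dist <= 1e-6) {
    abort("fruit centre lies on the branch line; pose undefined",
          class = "guavapose_degenerate_pose")
  }
  list(nearest_point = setNames(n, c("x", "y", "z")),
       pose = setNames(delta / dist, c("x", "y", "z")),
       distance_to_branch = dist)
}

#' Angle between an estimated and a reference pose
#'
#' \eqn{\theta = \mathrm{acos}(\tilde q^T q / (\|\tilde q\| \|q\|))} in
#' degrees, in `[0, 180]`. The cosine is clamped to `[-1, 1]` so rounding
#' can never produce `NaN`. Symmetric in its arguments and invariant to
#' positive rescaling of either vector.
#'
#' @param q_est,q_ref Non-zero 3-vectors.
#' @return Angle in degrees.
#' @examples
#' pose_error(c(0, 1, 0), c(1, 0, 0)) # 90
#' @export
pose_error <- function(q_est, q_ref) {
  n1 <- sqrt(sum(q_est^2)); n2 <- sqrt(sum(q_ref^2))
  if (n1 == 0 || n2 == 0) {
    abort("pose vectors must be non-zero", class = "guavapose_domain_error")
  }
  cosang <- sum(q_est * q_ref) / (n1 * n2)
  acos(min(max(cosang, -1), 1)) * 180 / pi
}

#' Estimate poses for all detected fruits
#'
#' Runs [assign_mother_branch()] and [estimate_pose()] for every
#' detection. Fruits that cannot be posed — no segments at all, or a
#' centre degenerate with its branch line — are reported in the
#' `"unposed"` attribute and appear with `NA` pose columns.
#'
#' @param detections Detection tibble from [detect_fruits()].
#' @param segments Segment tibble from [detect_line_segments()].
#' @param clamp Passed to [assign_mother_branch()].
#' @return A tibble with one row per fruit: `fruit_id`, centre
#'   `cx, cy, cz`, `branch` (mother segment index), nearest point
#'   `nx, ny, nz`, pose `qx, qy, qz`, `distance_to_branch` and `posed`
#'   (logical). Attribute `"unposed"`: the `fruit_id`s without a pose.
#' @export
estimate_all_poses <- function(detections, segments, clamp = FALSE) {
  rows <- purrr::map(seq_len(nrow(detections)), function(i) {
    det <- detections[i, ]
    center <- c(det$x, det$y, det$z)
    j <- assign_mother_branch(center, segments, clamp = clamp)
    base <- tibble(fruit_id = det$fruit_id,
                   cx = center[1], cy = center[2], cz = center[3],
                   branch = j,
                   nx = NA_real_, ny = NA_real_, nz = NA_real_,
                   qx = NA_real_, qy = NA_real_, qz = NA_real_,
                   distance_to_branch = NA_real_, posed = FALSE)
    if (is.na(j)) return(base)
    est <- tryCatch(estimate_pose(center, segments[j, ]),
                    guavapose_degenerate_pose = function(e) NULL)
    if (is.null(est)) return(base)
    np <- unname(est$nearest_point); q <- unname(est$pose)
    base$nx <- np[1]; base$ny <- np[2]; base$nz <- np[3]
    base$qx <- q[1]; base$qy <- q[2]; base$qz <- q[3]
    base$distance_to_branch <- est$distance_to_branch
    base$posed <- TRUE
    base
  })
  out <- if (length(rows) == 0) {
    tibble(fruit_id = integer(), cx = numeric(), cy = numeric(),
           cz = numeric(), branch = integer(), nx = numeric(),
           ny = numeric(), nz = numeric(), qx = numeric(), qy = numeric(),
           qz = numeric(), distance_to_branch = numeric(), posed = logical())
  } else {
    dplyr::bind_rows(rows)
  }
  attr(out, "unposed") <- out$fruit_id[!out$posed]
  out
}
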