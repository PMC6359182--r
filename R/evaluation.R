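#' Match detected fruit centres to ground truth
#'
#' One-to-one greedy matching: all prediction/truth pairs within `tol` are
#' sorted by distance and consumed nearest-first, each prediction and each
#' truth being used at most once. Unmatched predictions are false
#' positives; unmatched truths are false negatives. Sorting by distance
#' makes the result independent of input ordering (up to exact ties).
#'
#' @param pred_centers,gt_centers Data frames with `x`, `y`, `z` columns
#'   (mm) or n x 3 matrices; either may be empty.
#' @param tol Maximum centre distance for a match, mm (default 30 —
#'   roughly a fruit radius).
#' @return A list with counts `tp`, `fp`, `fn` and `matching`, a tibble
#'   with columns `pred`, `truth`, `distance`.
#' @export
match_detections <- function(pred_centers, gt_centers, tol = 30) {
  if (tol <= 0) abort("`tol` must be > 0", class = "guavapose_parameter_error")
  P <- if (is.null(pred_centers)) matrix(numeric(0), 0, 3) else as_xyz(pred_centers)
  G <- if (is.null(gt_centers)) matrix(numeric(0), 0, 3) else as_xyz(gt_centers)
  np <- nrow(P); ng <- nrow(G)
  matching <- tibble(pred = integer(), truth = integer(), distance = numeric())
  if (np > 0 && ng > 0) {
    d <- sqrt(pmax(outer(rowSums(P^2), rowSums(G^2), "+") -
                     2 * tcrossprod(P, G), 0))
    cand <- which(d <= tol, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_p <- logical(np); used_g <- logical(ng)
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_p[i] && !used_g[j]) {
          used_p[i] <- TRUE; used_g[j] <- TRUE; keep[k] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      matching <- tibble(pred = as.integer(cand[, 1]),
                         truth = as.integer(cand[, 2]),
                         distance = d[cand])
    }
  }
  tp <- nrow(matching)
  list(tp = tp, fp = np - tp, fn = ng - tp, matching = matching)
}

#' Detection precision and recall
#'
#' Precision is true positives over the number of detections
#' (`tp / (tp + fp)`); recall is true positives over the number of
#' ground-truth fruits (`tp / n_gt`). A 0/0 ratio is reported as `NA`.
#'
#' @param tp,fp Counts of true and false positive detections.
#' @param n_gt Number of ground-truth fruits.
#' @return A one-row tibble with `tp`, `fp`, `n_gt`, `precision`,
#'   `recall`.
#' @examples
#' precision_recall(225, 4, 237)
#' @export
precision_recall <- function(tp, fp, n_gt) {
  if (tp < 0 || fp < 0 || n_gt < 0) {
    abort("counts must be non-negative", class = "guavapose_parameter_error")
  }
  tibble(
    tp = as.integer(tp), fp = as.integer(fp), n_gt = as.integer(n_gt),
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (n_gt > 0) tp / n_gt else NA_real_
  )
}

#' Robust summary of pose angular errors
#'
#' Computes the median error and median absolute deviation
#' \deqn{MEDE = \mathrm{median}\{\theta_i\}, \quad
#'       MAD = \mathrm{median}\{|\theta_i - MEDE|\},}
#' which unlike mean/sd are not dragged by the occasional false mother
#' branch, plus the percentage of errors strictly below each angle limit
#' (default limits 45, 35, 25 degrees). Medians of even-length samples are
#' the mean of the two central values.
#'
#' @param errors Non-empty numeric vector of angular errors in degrees.
#' @param limits Angle limits (degrees) for the frequency table.
#' @return A list of class `pose_stats` with `errors`, `mede`, `mad` and
#'   `freq_within` (tibble `limit`, `percent`). [tidy()] returns the
#'   frequency table, [glance()] the one-row summary.
#' @examples
#' pose_stats(c(10, 20, 30)) # MEDE 20, MAD 10
#' @export
pose_stats <- function(errors, limits = c(45, 35, 25)) {
  if (length(errors) == 0) {
    abort("`errors` must be non-empty", class = "guavapose_parameter_error")
  }
  mede <- median(errors)
  mad <- median(abs(errors - mede))
  freq <- tibble(limit = as.numeric(limits),
                 percent = vapply(limits, function(L) 100 * mean(errors < L),
                                  numeric(1)))
  structure(list(errors = as.numeric(errors), mede = mede, mad = mad,
                 freq_within = freq),
            class = "pose_stats")
}

#' @export
print.pose_stats <- function(x, ...) {
  cat(sprintf("<pose_stats> n=%d  MEDE=%.2f deg  MAD=%.2f deg\n",
              length(x$errors), x$mede, x$mad))
  for (i in seq_len(nrow(x$freq_within))) {
    cat(sprintf("  < %g deg: %.2f%%\n",
                x$freq_within$limit[i], x$freq_within$percent[i]))
  }
  invisible(x)
}

#' @method tidy pose_stats
#' @export
tidy.pose_stats <- function(x, ...) x$freq_within

#' @method glance pose_stats
#' @export
glance.pose_stats <- function(x, ...) {
  tibble(n = length(x$errors), mede = x$mede, mad = x$mad)
}

#' Ground-truth pose from labelled point clouds
#'
#' Reference protocol for measuring a fruit's pose directly from labelled
#' data rather than from the reconstruction pipeline: the fruit centre is
#' estimated by a robust RANSAC sphere fit of the fruit's points, the
#' nearest point is taken point-wise from the labelled mother-branch cloud
#' (no line fitting), and the pose is the unit vector from that nearest
#' point to the centre.
#'
#' @param fruit_points Data frame with `x`, `y`, `z` of one fruit's
#'   points.
#' @param branch_points Data frame with `x`, `y`, `z` of its mother
#'   branch's points.
#' @param inlier_threshold,iterations,seed Passed to
#'   [fit_sphere_ransac()].
#' @return A one-row tibble: centre `cx, cy, cz`, nearest branch point
#'   `nx, ny, nz`, pose `qx, qy, qz`.
#' @export
ground_truth_pose <- function(fruit_points, branch_points,
                              inlier_threshold = 5, iterations = 1000,
                              seed = NULL) {
  fit <- fit_sphere_ransac(fruit_points, inlier_threshold, iterations,
                           seed = seed)
  ctr <- fit$center
  B <- as_xyz(branch_points)
  if (nrow(B) == 0) {
    abort("`branch_points` must be non-empty", class = "guavapose_parameter_error")
  }
  d2 <- rowSums(sweep(B, 2, ctr)^2)
  nearest <- unname(B[which.min(d2), ])
  ctr <- unname(ctr)
  q <- unitize(ctr - nearest, "pose")
  tibble(cx = ctr[1], cy = ctr[2], cz = ctr[3],
         nx = nearest[1], ny = nearest[2], nz = nearest[3],
         qx = q[1], qy = q[2], qz = q[3])
}
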