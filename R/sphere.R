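#' Bounding-box (centroid) fruit centre
#'
#' The cheap centre estimate: the arithmetic mean of a cluster's member
#' coordinates. For a single-view (hemispherical) sample of a fruit this
#' is biased toward the camera; the sphere fit is the precise alternative.
#'
#' @param points Data frame with `x`, `y`, `z` columns or n x 3 matrix;
#'   must be non-empty.
#' @return Named numeric vector `c(x, y, z)` in mm.
#' @export
center_bounding_box <- function(points) {
  xyz <- as_xyz(points)
  if (nrow(xyz) == 0) {
    abort("cannot compute the centre of an empty cluster",
          class = "guavapose_parameter_error")
  }
  colMeans(xyz)
}

#' Algebraic least-squares sphere fit
#'
#' Fits centre `c` and radius `r` by linearising the sphere equation:
#' \eqn{\|x\|^2 = 2 c \cdot x + (r^2 - \|c\|^2)} is linear in
#' \eqn{(c, r^2 - \|c\|^2)} and solved by QR least squares. Exact samples
#' of a sphere are recovered to numerical precision. Fewer than 4 points,
#' or a rank-deficient design (coplanar/collinear points), raises a
#' degenerate-fit error (condition class `guavapose_degenerate_fit`), on
#' which callers fall back to the bounding-box centre.
#'
#' @param points Data frame with `x`, `y`, `z` columns or n x 3 matrix;
#'   at least 4 non-coplanar points.
#' @return A list of class `sphere` with `center` (mm), `radius` (mm) and
#'   `rms` (root-mean-square surface residual of the fit points, mm).
#' @export
fit_sphere_lsq <- function(points) {
  xyz <- as_xyz(points)
  if (nrow(xyz) < 4) {
    abort("sphere fitting needs at least 4 points",
          class = "guavapose_degenerate_fit")
  }
  A <- cbind(2 * xyz, 1)
  b <- rowSums(xyz^2)
  qr_A <- qr(A)
  if (qr_A$rank < 4) {
    abort("degenerate sphere fit: points are coplanar or collinear",
          class = "guavapose_degenerate_fit")
  }
  beta <- qr.coef(qr_A, b)
  center <- beta[1:3]
  r2 <- beta[4] + sum(center^2)
  if (!is.finite(r2) || r2 <= 0) {
    abort("degenerate sphere fit: non-positive squared radius",
          class = "guavapose_degenerate_fit")
  }
  radius <- sqrt(r2)
  res <- sqrt(rowSums(sweep(xyz, 2, center)^2)) - radius
  structure(list(center = setNames(as.numeric(center), c("x", "y", "z")),
                 radius = as.numeric(radius),
                 rms = sqrt(mean(res^2))),
            class = "sphere")
}

#' @export
print.sphere <- function(x, ...) {
  cat(sprintf("<sphere> center (%.2f, %.2f, %.2f) mm, radius %.2f mm, rms %.3g mm\n",
              x$center[1], x$center[2], x$center[3], x$radius, x$rms))
  invisible(x)
}

#' Robust RANSAC sphere fit
#'
#' Sample-consensus sphere estimation for point sets contaminated by gross
#' outliers (the robust centre used when measuring ground-truth fruit
#' positions from hand-labelled clouds). Each iteration fits an exact
#' sphere through 4 random points and counts inliers whose distance to the
#' sphere surface is at most `inlier_threshold`; the consensus-maximising
#' model is refined with [fit_sphere_lsq()] on its inliers. Deterministic
#' for a given `seed`.
#'
#' @param points Data frame with `x`, `y`, `z` columns or n x 3 matrix
#'   (at least 4 points).
#' @param inlier_threshold Max distance from the sphere surface, mm.
#' @param iterations Number of minimal-sample draws.
#' @param radius_range Optional `c(min, max)` prior on plausible radii
#'   (mm); candidate models outside it are rejected. With a prior set, an
#'   all-outlier cloud yields no acceptable model.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A `sphere` object with an extra `n_inliers` field.
#'   Raises a condition of class `guavapose_ransac_failure` when no model
#'   reaches 4 inliers.
#' @export
fit_sphere_ransac <- function(points, inlier_threshold = 5, iterations = 1000,
                              radius_range = NULL, seed = NULL) {
  xyz <- as_xyz(points)
  n <- nrow(xyz)
  if (n < 4) {
    abort("RANSAC sphere fitting needs at least 4 points",
          class = "guavapose_ransac_failure")
  }
  with_seed(seed, {
    best_count <- 0L
    best_inliers <- NULL
    for (i in seq_len(iterations)) {
      samp <- sample.int(n, 4)
      model <- tryCatch(fit_sphere_lsq(xyz[samp, , drop = FALSE]),
                        guavapose_degenerate_fit = function(e) NULL)
      if (is.null(model)) next
      if (!is.null(radius_range) &&
          (model$radius < radius_range[1] || model$radius > radius_range[2])) {
        next
      }
      d <- abs(sqrt(rowSums(sweep(xyz, 2, model$center)^2)) - model$radius)
      inl <- which(d <= inlier_threshold)
      if (length(inl) > best_count) {
        best_count <- length(inl)
        best_inliers <- inl
      }
    }
    if (best_count < 4) {
      abort("RANSAC found no sphere model with at least 4 inliers",
            class = "guavapose_ransac_failure")
    }
    fit <- fit_sphere_lsq(xyz[best_inliers, , drop = FALSE])
    fit$n_inliers <- best_count
    fit
  })
}
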