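#' Detect individual fruits in a labelled point cloud
#'
#' Splits the fruit-class points (label 1) into individual fruits by
#' [euclidean_cluster()] and estimates a centre per cluster, either as the
#' cluster mean (`"bounding_box"`) or as the centre of an algebraic
#' least-squares sphere fit (`"sphere_fit"`, the more precise option for
#' near-spherical fruit). Degenerate sphere fits fall back to the
#' bounding-box centre; the `center_method` column records which was used
#' for each fruit.
#'
#' @param cloud A labelled point cloud tibble from [backproject()] (needs
#'   `x`, `y`, `z`; a `label` column restricts detection to label 1 —
#'   without one, all points are treated as fruit).
#' @param params A [cluster_params()] object.
#' @param center_method `"sphere_fit"` (default) or `"bounding_box"`.
#' @return A tibble with one row per detected fruit: `fruit_id`,
#'   `n_points`, centre `x`, `y`, `z` (mm), `center_method`,
#'   `sphere_radius` (mm, `NA` for bounding-box centres) and `members`
#'   (list-column of row indices into `cloud`).
#' @examples
#' cloud <- tibble::tibble(x = rnorm(50), y = rnorm(50), z = 1000 + rnorm(50),
#'                         label = 1L)
#' detect_fruits(cloud, cluster_params(4, 10), "bounding_box")
#' @export
detect_fruits <- function(cloud, params = cluster_params(),
                          center_method = c("sphere_fit", "bounding_box")) {
  center_method <- match.arg(center_method)
  stopifnot(is.data.frame(cloud))
  rows <- if ("label" %in% names(cloud)) which(cloud$label == 1L) else seq_len(nrow(cloud))
  empty <- tibble(fruit_id = integer(), n_points = integer(),
                  x = numeric(), y = numeric(), z = numeric(),
                  center_method = character(), sphere_radius = numeric(),
                  members = list())
  if (length(rows) == 0) return(empty)
  fruit_pts <- cloud[rows, c("x", "y", "z")]
  clusters <- euclidean_cluster(fruit_pts, params)
  if (length(clusters) == 0) return(empty)

  res <- purrr::imap(clusters, function(idx, i) {
    pts <- fruit_pts[idx, , drop = FALSE]
    method <- center_method
    radius <- NA_real_
    if (center_method == "sphere_fit") {
      fit <- tryCatch(fit_sphere_lsq(pts),
                      guavapose_degenerate_fit = function(e) NULL)
      if (is.null(fit)) {
        method <- "bounding_box"
        ctr <- center_bounding_box(pts)
      } else {
        ctr <- fit$center
        radius <- fit$radius
      }
    } else {
      ctr <- center_bounding_box(pts)
    }
    tibble(fruit_id = i, n_points = length(idx),
           x = ctr[1], y = ctr[2], z = ctr[3],
           center_method = method, sphere_radius = radius,
           members = list(rows[idx]))
  })
  dplyr::bind_rows(res)
}
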