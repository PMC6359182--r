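#' Plot a rendered scene
#'
#' Image-plane view of the label map with the ground-truth fruit centres
#' overlaid.
#'
#' @param object A `rendered_scene`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rendered_scene
#' @export
autoplot.rendered_scene <- function(object, ...) {
  lab <- object$labels
  df <- tidyr::expand_grid(v = 0:(nrow(lab) - 1), u = 0:(ncol(lab) - 1))
  df$class <- factor(as.vector(t(lab)), levels = 0:2,
                     labels = c("background", "fruit", "branch"))
  ctr <- project(dplyr::rename(object$truth_fruits,
                               x = "cx", y = "cy", z = "cz"),
                 object$camera)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$class)) +
    ggplot2::geom_point(data = ctr, shape = 3, colour = "white", size = 2) +
    ggplot2::scale_fill_manual(values = c(background = "grey15",
                                          fruit = "#d9534f",
                                          branch = "#5cb85c")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "u (px)", y = "v (px)", fill = NULL)
}

#' Plot pipeline results in the image plane
#'
#' Projects detected fruit centres, reconstructed branch segments and
#' pose arrows (fruit centre towards its nearest branch point) onto the
#' image plane.
#'
#' @param object A `guava_pipeline` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot guava_pipeline
#' @export
autoplot.guava_pipeline <- function(object, ...) {
  intr <- object$config$intrinsics
  cloud <- object$cloud
  cloud$class <- factor(cloud$label, levels = 0:2,
                        labels = c("background", "fruit", "branch"))
  p <- ggplot2::ggplot(cloud, ggplot2::aes(x = .data$u, y = .data$v)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 0.3) +
    ggplot2::scale_colour_manual(values = c(background = "grey70",
                                            fruit = "#d9534f",
                                            branch = "#5cb85c"))
  if (nrow(object$segments) > 0) {
    seg <- object$segments
    e1 <- project(cbind(seg$px + seg$s_min * seg$tx,
                        seg$py + seg$s_min * seg$ty,
                        seg$pz + seg$s_min * seg$tz), intr)
    e2 <- project(cbind(seg$px + seg$s_max * seg$tx,
                        seg$py + seg$s_max * seg$ty,
                        seg$pz + seg$s_max * seg$tz), intr)
    segdf <- tibble(u = e1$u, v = e1$v, uend = e2$u, vend = e2$v)
    p <- p + ggplot2::geom_segment(
      data = segdf,
      ggplot2::aes(x = .data$u, y = .data$v,
                   xend = .data$uend, yend = .data$vend),
      colour = "black", linewidth = 0.8)
  }
  posed <- dplyr::filter(object$poses, .data$posed)
  if (nrow(posed) > 0) {
    cuv <- project(dplyr::rename(posed, x = "cx", y = "cy", z = "cz"), intr)
    nuv <- project(dplyr::rename(posed, x = "nx", y = "ny", z = "nz"), intr)
    arrows <- tibble(u = nuv$u, v = nuv$v, uend = cuv$u, vend = cuv$v)
    p <- p + ggplot2::geom_segment(
      data = arrows,
      ggplot2::aes(x = .data$u, y = .data$v,
                   xend = .data$uend, yend = .data$vend),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "gold3", linewidth = 0.7)
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(x = "u (px)", y = "v (px)", colour = NULL)
}

#' Histogram of pose angular errors
#'
#' @param object A [pose_stats()] object.
#' @param binwidth Histogram bin width in degrees.
#' @param ... Unused.
#' @return A ggplot object with the median error marked.
#' @method autoplot pose_stats
#' @export
autoplot.pose_stats <- function(object, binwidth = 5, ...) {
  df <- tibble(theta = object$errors)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$mede, colour = "#d9534f") +
    ggplot2::labs(x = "pose error (degrees)", y = "count",
                  subtitle = sprintf("MEDE %.2f deg, MAD %.2f deg",
                                     object$mede, object$mad))
}
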