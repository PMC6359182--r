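#' Morphological skeleton of a binary mask
#'
#' Thins a binary branch mask to its 1-pixel-wide medial representation by
#' the classical erosion/opening construction
#' \deqn{S = \bigcup_{k=0}^{K} (A \ominus kB) - (A \ominus kB) \circ B,}
#' where \eqn{A \ominus kB} is `k` successive erosions of the mask by the
#' structuring element `B`, \eqn{\circ} is morphological opening, and `K`
#' is the largest `k` for which the eroded mask is non-empty. The skeleton
#' is always a subset of the mask, and a 1-pixel-wide line is its own
#' skeleton. Reducing a thick branch blob to its skeleton cuts the branch
#' point cloud to a size the line detector can process quickly.
#'
#' @param mask Logical (or 0/1) matrix; `TRUE` marks branch pixels.
#' @param brush_size Side of the square structuring element in pixels
#'   (odd; default 3, i.e. 8-connected thinning).
#' @return A logical matrix of the same dimensions.
#' @export
skeletonize <- function(mask, brush_size = 3) {
  stopifnot(is.matrix(mask))
  A <- (mask != 0) * 1
  if (!any(A == 1)) return(matrix(FALSE, nrow(A), ncol(A)))
  B <- EBImage::makeBrush(brush_size, shape = "box")
  S <- matrix(FALSE, nrow(A), ncol(A))
  Ak <- A
  while (any(Ak > 0.5)) {
    opened <- EBImage::opening(Ak, B)
    S <- S | (Ak > 0.5 & opened < 0.5)
    Ak <- EBImage::erode(Ak, B)
  }
  S
}
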