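#' Baseline colour-rule segmentation
#'
#' A deterministic per-pixel stand-in segmenter for workflows where no
#' trained model is available: a pixel is classed as fruit or branch when
#' its RGB values satisfy simple dominance rules, otherwise background.
#' Any externally produced 3-class map (for example the output of a
#' trained network, loaded with [read_labels()]) can be used everywhere a
#' segmentation is expected; this baseline only exists so the geometric
#' pipeline can run end-to-end without one.
#'
#' The default rules target the package's synthetic renders (red fruits,
#' green branches): fruit when `r >= fruit_min` and `r` exceeds both other
#' channels by `fruit_dominance`; branch when `g >= branch_min` and `g`
#' exceeds both other channels by `branch_dominance`. Fruit wins where
#' both rules fire.
#'
#' @param rgb `rows x cols x 3` numeric array with channels in `[0, 1]`.
#' @param rules A list as produced by [baseline_rules()].
#' @return An integer matrix of class codes `{0, 1, 2}` with the image's
#'   dimensions.
#' @export
segment_baseline <- function(rgb, rules = baseline_rules()) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] < 3) {
    abort("`rgb` must be a rows x cols x 3 array",
          class = "guavapose_parameter_error")
  }
  rules <- validate_baseline_rules(rules)
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  fruit <- r >= rules$fruit_min &
    (r - g) >= rules$fruit_dominance & (r - b) >= rules$fruit_dominance
  branch <- g >= rules$branch_min &
    (g - r) >= rules$branch_dominance & (g - b) >= rules$branch_dominance
  out <- matrix(0L, nrow(r), ncol(r))
  out[branch] <- 2L
  out[fruit] <- 1L
  out
}

#' @rdname segment_baseline
#' @param fruit_min,fruit_dominance,branch_min,branch_dominance Channel
#'   thresholds in `[0, 1]` for the two colour rules.
#' @export
baseline_rules <- function(fruit_min = 0.5, fruit_dominance = 0.15,
                           branch_min = 0.35, branch_dominance = 0.1) {
  validate_baseline_rules(list(
    fruit_min = fruit_min, fruit_dominance = fruit_dominance,
    branch_min = branch_min, branch_dominance = branch_dominance))
}

validate_baseline_rules <- function(rules) {
  need <- c("fruit_min", "fruit_dominance", "branch_min", "branch_dominance")
  if (!is.list(rules) || !all(need %in% names(rules)) ||
      !all(vapply(rules[need], function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x), logical(1)))) {
    abort("malformed baseline segmentation rules",
          class = "guavapose_parameter_error")
  }
  rules[need]
}

#' Confusion matrix between predicted and true segmentations
#'
#' Counts `n[i, j]`, the number of pixels of true class `i` predicted as
#' class `j`, over the three classes background/fruit/branch.
#'
#' @param pred,truth Integer matrices of class codes `{0, 1, 2}` with
#'   identical dimensions.
#' @return A 3 x 3 integer matrix of class `seg_confusion` (rows = true
#'   class, columns = predicted class).
#' @seealso [class_metrics()] for per-class accuracy and IOU;
#'   [tidy()]/[glance()] methods are provided.
#' @export
confusion <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) {
    abort("`pred` and `truth` must have identical dimensions",
          class = "guavapose_parameter_error")
  }
  classes <- c("background", "fruit", "branch")
  cm <- table(
    factor(truth, levels = 0:2, labels = classes),
    factor(pred, levels = 0:2, labels = classes)
  )
  cm <- matrix(as.integer(cm), 3, 3, dimnames = list(true = classes, pred = classes))
  structure(cm, class = c("seg_confusion", "matrix"))
}

#' Per-class segmentation metrics
#'
#' From a confusion matrix with entries \eqn{n_{ij}} and row sums
#' \eqn{t_i}, computes for each class the pixel accuracy
#' \eqn{acc_i = n_{ii} / t_i} and intersection over union
#' \eqn{IOU_i = n_{ii} / (t_i + \sum_j n_{ji} - n_{ii})}. Classes absent
#' from the ground truth (`t_i = 0`) are reported as `NA` and excluded
#' from the means returned by [glance()].
#'
#' @param cm A `seg_confusion` matrix from [confusion()].
#' @return A tibble with columns `class`, `n_true`, `accuracy`, `iou`.
#' @export
class_metrics <- function(cm) {
  stopifnot(inherits(cm, "seg_confusion"))
  m <- unclass(cm)
  ti <- rowSums(m)
  nii <- diag(m)
  col <- colSums(m)
  acc <- ifelse(ti > 0, nii / ti, NA_real_)
  iou_den <- ti + col - nii
  iou <- ifelse(ti > 0, nii / iou_den, NA_real_)
  tibble(
    class = rownames(m),
    n_true = as.integer(ti),
    accuracy = as.numeric(acc),
    iou = as.numeric(iou)
  )
}

#' @method tidy seg_confusion
#' @export
tidy.seg_confusion <- function(x, ...) class_metrics(x)

#' @method glance seg_confusion
#' @export
glance.seg_confusion <- function(x, ...) {
  per <- class_metrics(x)
  ok <- !is.na(per$accuracy)
  tibble(
    mean_accuracy = mean(per$accuracy[ok]),
    mean_iou = mean(per$iou[ok]),
    n_pixels = sum(unclass(x)),
    n_classes = sum(ok)
  )
}

#' @export
print.seg_confusion <- function(x, ...) {
  cat("<seg_confusion> rows = true class, cols = predicted\n")
  print(unclass(x))
  invisible(x)
}
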