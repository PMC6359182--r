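test_that("baseline colour rules segment toy images deterministically", {
  # all-black image is all background
  black <- array(0, c(8, 8, 3))
  expect_true(all(segment_baseline(black) == 0L))

  # one fruit-coloured disk on black: the fruit region is exactly the disk
  img <- array(0, c(10, 10, 3))
  disk <- outer(1:10, 1:10, function(r, c) (r - 5)^2 + (c - 5)^2 <= 9)
  img[, , 1][disk] <- 0.9; img[, , 2][disk] <- 0.2; img[, , 3][disk] <- 0.1
  seg <- segment_baseline(img)
  expect_identical(seg == 1L, disk)
  expect_true(all(seg[!disk] == 0L))

  # branch-coloured stripe
  img2 <- array(0, c(6, 6, 3))
  img2[3, , 1] <- 0.25; img2[3, , 2] <- 0.6; img2[3, , 3] <- 0.2
  expect_true(all(segment_baseline(img2)[3, ] == 2L))

  expect_error(segment_baseline(array(0, c(4, 4))),
               class = "guavapose_parameter_error")
  expect_error(segment_baseline(black, rules = list(fruit_min = "a")),
               class = "guavapose_parameter_error")
})

test_that("an externally produced label map passes through I/O unchanged", {
  sc <- scene_preset("single_fruit")
  f <- withr::local_tempfile(fileext = ".png")
  write_labels(sc$labels, f)
  expect_identical(read_labels(f), sc$labels)
})

test_that("confusion counts pixels exactly", {
  # 2x2 toy counted by hand: truth = [1,1;0,0], pred = [1,0;0,0]
  truth <- matrix(c(1L, 0L, 1L, 0L), 2, 2)
  pred <- matrix(c(1L, 0L, 0L, 0L), 2, 2)
  cm <- confusion(pred, truth)
  m <- unclass(cm)
  expect_equal(m["fruit", "fruit"], 1L)
  expect_equal(m["fruit", "background"], 1L)
  expect_equal(m["background", "background"], 2L)
  expect_equal(sum(m), 4L)

  # perfect prediction is diagonal
  cmd <- confusion(truth, truth)
  expect_equal(sum(unclass(cmd)) , sum(diag(unclass(cmd))))

  # disjoint classes land entirely off-diagonal
  cmo <- confusion(matrix(1L, 2, 2), matrix(2L, 2, 2))
  expect_equal(sum(diag(unclass(cmo))), 0L)

  expect_error(confusion(matrix(0L, 2, 2), matrix(0L, 3, 3)),
               class = "guavapose_parameter_error")
})

test_that("per-class accuracy and IOU match hand evaluation", {
  # perfect prediction: both metrics 1 for present classes
  truth <- matrix(rep(0:2, each = 10), 5, 6)
  per <- class_metrics(confusion(truth, truth))
  expect_equal(per$accuracy, rep(1, 3))
  expect_equal(per$iou, rep(1, 3))

  # nii = 8, ti = 10, column sum = 12: accuracy 0.8, IOU 8/14
  m <- matrix(0L, 3, 3, dimnames = list(true = c("background", "fruit", "branch"),
                                        pred = c("background", "fruit", "branch")))
  m[2, 2] <- 8L; m[2, 1] <- 2L; m[1, 2] <- 4L; m[1, 1] <- 6L
  cm <- structure(m, class = c("seg_confusion", "matrix"))
  per <- class_metrics(cm)
  expect_equal(per$accuracy[per$class == "fruit"], 0.8)
  expect_equal(per$iou[per$class == "fruit"], 8 / 14)

  # nii = 0 with ti > 0: both zero; absent class undefined
  expect_equal(per$accuracy[per$class == "branch"], NA_real_)
  g <- glance(cm)
  expect_equal(g$n_classes, 2L)
})

test_that("IOU never exceeds accuracy and both live in [0, 1]", {
  set.seed(42)
  for (i in 1:100) {
    m <- matrix(as.integer(rpois(9, lambda = sample(c(1, 20, 300), 1))), 3, 3,
                dimnames = list(true = c("background", "fruit", "branch"),
                                pred = c("background", "fruit", "branch")))
    cm <- structure(m, class = c("seg_confusion", "matrix"))
    per <- class_metrics(cm)
    ok <- !is.na(per$accuracy)
    expect_true(all(per$iou[ok] <= per$accuracy[ok] + 1e-12))
    expect_true(all(per$iou[ok] >= 0 & per$iou[ok] <= 1))
    expect_true(all(per$accuracy[ok] >= 0 & per$accuracy[ok] <= 1))
    # metric equals 1 iff the class row and column are purely diagonal
    for (k in which(ok)) {
      diag_only <- m[k, k] == sum(m[k, ]) && m[k, k] == sum(m[, k])
      expect_equal(per$iou[k] == 1, diag_only)
    }
  }
})

test_that("swapping class ids permutes the confusion matrix consistently", {
  set.seed(7)
  truth <- matrix(sample(0:2, 100, replace = TRUE), 10, 10)
  pred <- matrix(sample(0:2, 100, replace = TRUE), 10, 10)
  cm <- unclass(confusion(pred, truth))
  swap <- function(m) { m[m == 1L] <- 9L; m[m == 2L] <- 1L; m[m == 9L] <- 2L; m }
  cm2 <- unclass(confusion(swap(pred), swap(truth)))
  perm <- c(1, 3, 2)
  expect_equal(unname(cm2), unname(cm[perm, perm]))
})
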