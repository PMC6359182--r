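test_that("point-line distance matches the cross-product identity", {
  expect_equal(point_line_distance(c(5, 0, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(point_line_distance(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 1)

  set.seed(23)
  for (i in 1:25) {
    p <- rnorm(3, 0, 100)
    t <- rnorm(3); t <- t / sqrt(sum(t^2))
    cpt <- rnorm(3, 0, 100)
    want <- sqrt(sum(crossprod_vec(cpt - p, t)^2))
    expect_equal(point_line_distance(cpt, p, t), want, tolerance = 1e-12)
  }

  expect_warning(d <- point_line_distance(c(0, 2, 0), c(0, 0, 0), c(3, 0, 0)),
                 "unit")
  expect_equal(d, 2)
})

test_that("a single noiseless line is recovered with all points as inliers", {
  pts <- sample_line(100, c(10, -5, 900), c(2, 1, 0.5), span = 300)
  segs <- detect_line_segments(pts, line_params(15, 500, 40), seed = 1)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_inliers, 100L)
  truth <- c(2, 1, 0.5) / sqrt(sum(c(2, 1, 0.5)^2))
  expect_lt(axis_angle(c(segs$tx, segs$ty, segs$tz), truth), 0.1)
  expect_equal(sqrt(segs$tx^2 + segs$ty^2 + segs$tz^2), 1, tolerance = 1e-9)
  expect_gt(segs$s_max - segs$s_min, 290)
})

test_that("two separated perpendicular lines give two matched segments", {
  pts <- dplyr::bind_rows(
    sample_line(60, c(0, 0, 900), c(1, 0, 0), span = 250),
    sample_line(60, c(0, 200, 900), c(0, 1, 0), span = 250))
  segs <- detect_line_segments(pts, line_params(15, 1000, 40), seed = 2)
  expect_equal(nrow(segs), 2)
  angs <- sapply(list(c(1, 0, 0), c(0, 1, 0)), function(truth) {
    min(sapply(seq_len(2), function(k)
      axis_angle(c(segs$tx[k], segs$ty[k], segs$tz[k]), truth)))
  })
  expect_true(all(angs < 1))
  # bookkeeping: inlier sets disjoint, each strictly above the threshold
  expect_equal(length(intersect(segs$inliers[[1]], segs$inliers[[2]])), 0)
  expect_true(all(segs$n_inliers > 40))
})

test_that("clouds below the acceptance threshold give no segments", {
  pts <- sample_line(30, c(0, 0, 900), c(1, 0, 0), span = 200)
  segs <- detect_line_segments(pts, line_params(15, 500, 40), seed = 3)
  expect_equal(nrow(segs), 0)
  expect_equal(nrow(detect_line_segments(
    tibble::tibble(x = numeric(), y = numeric(), z = numeric()))), 0)
})

test_that("directions follow the non-negative-z sign convention", {
  set.seed(29)
  for (i in 1:10) {
    t <- rnorm(3); t <- t / sqrt(sum(t^2))
    pts <- sample_line(80, rnorm(3, 0, 50) + c(0, 0, 900), t, span = 300,
                       sigma = 1)
    segs <- detect_line_segments(pts, line_params(15, 400, 40), seed = i)
    expect_equal(nrow(segs), 1)
    expect_gte(segs$tz, 0)
  }
})

test_that("three noisy branch axes are each matched by exactly one segment", {
  set.seed(33)
  axes <- list(c(1, 0, 0), c(0.970, -0.243, 0), c(0.447, 0.894, 0.1))
  anchors <- list(c(-150, -80, 900), c(-150, 60, 1000), c(-50, -120, 1100))
  pts <- dplyr::bind_rows(purrr::map2(axes, anchors, function(a, p)
    sample_line(150, p, a, span = 320, sigma = 2)))
  segs <- detect_line_segments(pts, line_params(15, 4000, 40), seed = 7)
  expect_equal(nrow(segs), 3)
  used <- integer(0)
  for (a in seq_along(axes)) {
    angs <- sapply(seq_len(3), function(k)
      axis_angle(c(segs$tx[k], segs$ty[k], segs$tz[k]),
                 axes[[a]] / sqrt(sum(axes[[a]]^2))))
    k <- which.min(angs)
    expect_lt(angs[k], 2)
    # perpendicular offset of the fitted line from the true axis
    offs <- point_line_distance(c(segs$px[k], segs$py[k], segs$pz[k]),
                                anchors[[a]],
                                axes[[a]] / sqrt(sum(axes[[a]]^2)))
    expect_lt(offs, 5)
    used <- c(used, k)
  }
  expect_equal(sort(used), 1:3)  # one-to-one matching
})

test_that("branches collinear in 2D but split in depth give two 3D segments", {
  sc <- scene_preset("collinear_2d_depth_split")
  segs <- reconstruct_branches(sc$labels, sc$depth, sc$camera,
                               line_params(), seed = 11)
  expect_equal(nrow(segs), 2)
  expect_gt(abs(segs$pz[1] - segs$pz[2]), 100)
  # and both project onto (nearly) the same image line
  tr <- sc$truth_branches
  expect_equal(tr$py / tr$pz, c(0, 0))
})

test_that("frames without branch pixels reconstruct to nothing", {
  lab <- matrix(0L, 40, 40)
  depth <- matrix(1000, 40, 40)
  segs <- reconstruct_branches(lab, depth, default_camera())
  expect_equal(nrow(segs), 0)
})
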