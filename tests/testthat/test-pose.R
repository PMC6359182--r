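seg_row <- function(p, t, s_min = -100, s_max = 100) {
  t <- t / sqrt(sum(t^2))
  tibble::tibble(segment_id = 1L, px = p[1], py = p[2], pz = p[3],
                 tx = t[1], ty = t[2], tz = t[3],
                 s_min = s_min, s_max = s_max, n_inliers = 50L,
                 inliers = list(integer()))
}

test_that("mother-branch assignment minimises line distance with tie rule", {
  segs <- seg_row(c(0, 0, 0), c(1, 0, 0))
  expect_equal(assign_mother_branch(c(0, 100, 0), segs), 1L)

  # evaluated by hand: x-axis at distance 100 beats a parallel line at z = 500
  two <- dplyr::bind_rows(seg_row(c(0, 0, 0), c(1, 0, 0)),
                          seg_row(c(0, 0, 500), c(1, 0, 0)))
  two$segment_id <- 1:2
  expect_equal(assign_mother_branch(c(0, 100, 0), two), 1L)

  # exact tie: the smaller index wins
  sym <- dplyr::bind_rows(seg_row(c(0, -50, 0), c(1, 0, 0)),
                          seg_row(c(0, 50, 0), c(1, 0, 0)))
  expect_equal(assign_mother_branch(c(0, 0, 0), sym), 1L)

  expect_true(is.na(assign_mother_branch(c(0, 0, 0), NULL)))
})

test_that("clamped assignment uses the finite extent", {
  # the infinite line of segment 1 passes close, but its extent ends far away
  far <- seg_row(c(1000, 5, 0), c(1, 0, 0), s_min = 0, s_max = 50)
  near <- seg_row(c(0, 0, 30), c(0, 1, 0), s_min = -100, s_max = 100)
  segs <- dplyr::bind_rows(far, near); segs$segment_id <- 1:2
  expect_equal(assign_mother_branch(c(0, 0, 0), segs), 1L)          # false mother
  expect_equal(assign_mother_branch(c(0, 0, 0), segs, clamp = TRUE), 2L)
})

test_that("pose formulas reproduce the closed form", {
  seg <- seg_row(c(0, 0, 0), c(1, 0, 0))
  est <- estimate_pose(c(0, 100, 0), seg)
  expect_equal(unname(est$nearest_point), c(0, 0, 0))
  expect_equal(unname(est$pose), c(0, 1, 0))
  expect_equal(est$distance_to_branch, 100)

  # anchored away from the foot point
  seg2 <- seg_row(c(-7, 3, 900), c(0, 0, 1))
  est2 <- estimate_pose(c(5, 3, 1200), seg2)
  expect_equal(unname(est2$nearest_point), c(-7, 3, 1200))
  expect_equal(unname(est2$pose), c(1, 0, 0))

  # translation invariance of the pose direction
  shift <- c(13, -44, 250)
  seg3 <- seg_row(c(0, 0, 0) + shift, c(1, 0, 0))
  est3 <- estimate_pose(c(0, 100, 0) + shift, seg3)
  expect_equal(unname(est3$pose), c(0, 1, 0))

  expect_error(estimate_pose(c(50, 0, 0), seg),
               class = "guavapose_degenerate_pose")
})

test_that("pose error is the clamped angle in degrees", {
  expect_equal(pose_error(c(0, 1, 0), c(0, 1, 0)), 0)
  expect_equal(pose_error(c(0, 1, 0), c(1, 0, 0)), 90)
  expect_equal(pose_error(c(0, 1, 0), c(0, -1, 0)), 180)
  # invariant to positive scaling and symmetric
  expect_equal(pose_error(c(0, 2, 0), c(3, 0, 0)), 90)
  expect_equal(pose_error(c(1, 2, 3), c(3, 1, 2)),
               pose_error(c(3, 1, 2), c(1, 2, 3)))
  # cosines pushed past 1 by rounding are clamped, never NaN
  v <- c(1, 1, 1) / sqrt(3)
  expect_false(is.nan(pose_error(v, v * (1 + 1e-15))))
  expect_error(pose_error(c(0, 0, 0), c(1, 0, 0)),
               class = "guavapose_domain_error")
})

test_that("all emitted poses are perpendicular to their mother branch", {
  set.seed(41)
  segs <- dplyr::bind_rows(lapply(1:3, function(k) {
    s <- seg_row(rnorm(3, 0, 200), rnorm(3))
    s$segment_id <- k
    s
  }))
  dets <- tibble::tibble(fruit_id = 1:6,
                         x = rnorm(6, 0, 150), y = rnorm(6, 0, 150),
                         z = rnorm(6, 900, 100))
  poses <- estimate_all_poses(dets, segs)
  expect_true(all(poses$posed))
  for (i in 1:6) {
    j <- poses$branch[i]
    dot <- poses$qx[i] * segs$tx[j] + poses$qy[i] * segs$ty[j] +
      poses$qz[i] * segs$tz[j]
    expect_lt(abs(dot), 1e-9)
    qn <- sqrt(poses$qx[i]^2 + poses$qy[i]^2 + poses$qz[i]^2)
    expect_equal(qn, 1, tolerance = 1e-9)
  }
})

test_that("poses are equivariant under scene rotation", {
  set.seed(43)
  seg <- seg_row(c(10, -20, 950), c(2, 1, 2))
  centre <- c(60, 30, 1000)
  base <- estimate_pose(centre, seg)
  for (i in 1:20) {
    R <- random_rotation()
    segR <- seg_row(as.vector(R %*% c(seg$px, seg$py, seg$pz)),
                    as.vector(R %*% c(seg$tx, seg$ty, seg$tz)))
    rot <- estimate_pose(as.vector(R %*% centre), segR)
    expect_equal(unname(rot$pose), as.vector(R %*% base$pose),
                 tolerance = 1e-9)
  }
})

test_that("fruits without branches are reported unposed", {
  dets <- tibble::tibble(fruit_id = 1:2, x = c(0, 5), y = c(0, 5),
                         z = c(900, 905))
  empty_segs <- detect_line_segments(
    tibble::tibble(x = numeric(), y = numeric(), z = numeric()))
  poses <- estimate_all_poses(dets, empty_segs)
  expect_equal(nrow(poses), 2)
  expect_false(any(poses$posed))
  expect_equal(attr(poses, "unposed"), 1:2)
})
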