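test_that("scene construction places fruits by summed radii along the offset", {
  spec <- scene_spec(
    branches = tibble::tibble(x = 0, y = 0, z = 1000, ax = 1, ay = 0, az = 0,
                              length = 300, radius = 10),
    fruits = tibble::tibble(branch = 1L, attach = 0, ox = 0, oy = 1, oz = 0,
                            pedicel = 20, radius = 40))
  scene <- build_scene(spec)
  tf <- scene$truth_fruits
  expect_equal(c(tf$cx, tf$cy, tf$cz), c(0, 70, 1000))
  expect_equal(c(tf$qx, tf$qy, tf$qz), c(0, 1, 0))
  expect_equal(c(tf$nx, tf$ny, tf$nz), c(0, 0, 1000))

  # no fruits: empty truth table
  empty <- build_scene(scene_spec(spec$branches))
  expect_equal(nrow(empty$truth_fruits), 0)

  # offsets must be perpendicular to the mother axis
  expect_error(scene_spec(
    branches = spec$branches,
    fruits = tibble::tibble(branch = 1L, attach = 0, ox = 1, oy = 0.2, oz = 0,
                            pedicel = 20, radius = 40)),
    class = "guavapose_parameter_error")
})

test_that("every fruit pose is perpendicular to its mother axis by construction", {
  sc <- scene_preset("three_branch_canopy")
  tf <- sc$truth_fruits; tb <- sc$truth_branches
  for (i in seq_len(nrow(tf))) {
    j <- tf$branch[i]
    dot <- tf$qx[i] * tb$tx[j] + tf$qy[i] * tb$ty[j] + tf$qz[i] * tb$tz[j]
    expect_lt(abs(dot), 1e-9)
    expect_equal(tf$qx[i]^2 + tf$qy[i]^2 + tf$qz[i]^2, 1, tolerance = 1e-9)
  }
})

test_that("ray casting stores z-depth with analytic accuracy", {
  # sphere of radius 40 centred on the optical axis at 1000 mm:
  # the principal ray hits the front pole at depth 960
  spec <- scene_spec(
    branches = tibble::tibble(x = -0.5, y = -70, z = 1000, ax = 1, ay = 0,
                              az = 0, length = 1, radius = 0.5),
    fruits = tibble::tibble(branch = 1L, attach = 0.5, ox = 0, oy = 1, oz = 0,
                            pedicel = 29.5, radius = 40))
  sc <- render_scene(build_scene(spec))
  expect_equal(sc$truth_fruits$cy, 0)
  pp <- sc$depth[213, 257]  # pixel (u, v) = (256, 212), 0-based
  expect_equal(pp, 960, tolerance = 1e-6)
  expect_equal(sc$labels[213, 257], 1L)

  # every rendered fruit point lies on the sphere surface (noiseless)
  cloud <- backproject(sc$depth, sc$camera, labels = sc$labels,
                       mask = sc$labels == 1L)
  r_err <- abs(sqrt(cloud$x^2 + cloud$y^2 + (cloud$z - 1000)^2) - 40)
  expect_lt(max(r_err), 1e-6)
})

test_that("the z-buffer keeps the nearer object and empty scenes render empty", {
  # fruit in front of a thick branch along the same rays
  spec <- scene_spec(
    branches = tibble::tibble(x = -100, y = 0, z = 1000, ax = 1, ay = 0, az = 0,
                              length = 200, radius = 30),
    fruits = tibble::tibble(branch = 1L, attach = 100, ox = 0, oy = 0, oz = -1,
                            pedicel = 10, radius = 35))
  sc <- render_scene(build_scene(spec))
  expect_equal(sc$labels[213, 257], 1L)   # fruit wins the centre pixel
  expect_lt(sc$depth[213, 257], 1000 - 30)

  empty <- render_scene(build_scene(scene_spec(
    tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                   ax = numeric(), ay = numeric(), az = numeric(),
                   length = numeric(), radius = numeric()))))
  expect_true(all(empty$depth == 0))
  expect_true(all(empty$labels == 0L))
})

test_that("depth noise is seeded, positive, and confined to valid pixels", {
  spec <- scene_spec(
    branches = tibble::tibble(x = -100, y = 0, z = 900, ax = 1, ay = 0, az = 0,
                              length = 200, radius = 10),
    noise_sigma = 32)
  a <- render_scene(build_scene(spec), seed = 5)
  b <- render_scene(build_scene(spec), seed = 5)
  c3 <- render_scene(build_scene(spec), seed = 6)
  expect_identical(a$depth, b$depth)
  expect_false(identical(a$depth, c3$depth))
  expect_true(all(a$depth >= 0))
  noiseless <- render_scene(build_scene(scene_spec(spec$branches)))
  expect_identical(a$depth == 0, noiseless$depth == 0)
})

test_that("a rendered single-view cap supports sub-millimetre sphere fits", {
  sc <- scene_preset("single_fruit")
  cloud <- backproject(sc$depth, sc$camera, labels = sc$labels,
                       mask = sc$labels == 1L)
  expect_gt(nrow(cloud), 200)
  fit <- fit_sphere_lsq(cloud)
  truth <- c(sc$truth_fruits$cx, sc$truth_fruits$cy, sc$truth_fruits$cz)
  expect_lt(sqrt(sum((fit$center - truth)^2)), 0.5)
  expect_lt(abs(fit$radius - sc$truth_fruits$radius), 0.5)
  rob <- fit_sphere_ransac(cloud, seed = 8)
  expect_lt(sqrt(sum((rob$center - truth)^2)), 0.5)
})

test_that("presets encode their documented constructions", {
  one <- scene_preset("single_fruit")
  expect_equal(nrow(one$truth_fruits), 1)

  touching <- scene_preset("two_touching_fruits")
  tf <- touching$truth_fruits
  sep <- sqrt((tf$cx[1] - tf$cx[2])^2 + (tf$cy[1] - tf$cy[2])^2 +
                (tf$cz[1] - tf$cz[2])^2)
  expect_lt(sep - tf$radius[1] - tf$radius[2], 4)  # surfaces closer than 4 mm

  split2d <- scene_preset("collinear_2d_depth_split")
  tb <- split2d$truth_branches
  expect_gt(abs(tb$pz[1] - tb$pz[2]), 100)
  # both axes project into the image row of the principal point
  cam <- split2d$camera
  expect_equal(cam$fy * tb$py / tb$pz + cam$uy, rep(cam$uy, 2))

  noon <- attr(scene_preset("noisy_noon"), "spec")
  expect_equal(noon$noise_sigma, 32)

  expect_error(scene_preset("no_such_scene"))
})

test_that("scenes write to disk as plain-text-compatible formats", {
  sc <- scene_preset("single_fruit")
  dir <- withr::local_tempdir()
  write_scene(sc, dir)
  expect_true(all(file.exists(file.path(
    dir, c("depth.tif", "labels.png", "rgb.png", "truth.json",
           "intrinsics.yaml")))))
  d <- read_depth(file.path(dir, "depth.tif"))
  expect_lt(max(abs(d - sc$depth)), 0.5)   # integer-mm quantisation
  expect_identical(read_labels(file.path(dir, "labels.png")), sc$labels)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth$fruits), 1)
})
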