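# Renderer ground truth and the preprocessing utilities.

test_that("Lambertian limit: zero specular strength means I = A*S", {
  seqq <- render_sequence(scene_spec(resolution = 48L, n_frames = 2L,
                                     specular_strength = 0))
  fr <- seqq[[1]]
  expect_true(all(fr$gt$M == 0))
  AS <- pmin(pmax(fr$gt$A * array(fr$gt$S, dim(fr$gt$A)), 0), 1)
  expect_equal(fr$frame$pixels, AS, tolerance = 1e-12)
})

test_that("fronto-parallel plane renders constant depth", {
  seqq <- render_sequence(scene_spec(geometry = "plane", plane_depth = 2,
                                     resolution = 32L, n_frames = 1L,
                                     wobble = 0, specular_strength = 0))
  D <- seqq[[1]]$gt$D$values
  expect_equal(D, matrix(2, 32, 32), tolerance = 1e-12)
})

test_that("tube depth matches the scalar ray-cylinder oracle", {
  sp <- scene_spec(resolution = 32L, n_frames = 1L, wobble = 0,
                   fold_amp = 0, specular_strength = 0)
  seqq <- render_sequence(sp)
  fr <- seqq[[1]]
  K <- fr$K
  o <- fr$pose$t
  row <- 17
  for (col in c(1, 8, 16, 25, 32)) {
    d <- c((col - 1 - K$cx) / K$fx, (row - 1 - K$cy) / K$fy, 1)
    s_cyl <- oracle_ray_cylinder(o, d, sp$radius)
    s_cap <- (sp$length - o[3]) / d[3]
    expect_equal(fr$gt$D$values[row, col], min(s_cyl, s_cap), tolerance = 1e-6)
  }
})

test_that("rendering is deterministic in the seed", {
  a <- render_sequence(scene_spec(resolution = 32L, n_frames = 3L, seed = 5))
  b <- render_sequence(scene_spec(resolution = 32L, n_frames = 3L, seed = 5))
  c <- render_sequence(scene_spec(resolution = 32L, n_frames = 3L, seed = 6))
  expect_identical(a[[2]]$frame$pixels, b[[2]]$frame$pixels)
  expect_identical(a[[2]]$gt$D$values, b[[2]]$gt$D$values)
  expect_false(identical(a[[2]]$frame$pixels, c[[2]]$frame$pixels))
})

test_that("cross-view photoconsistency holds off speculars and fails on them", {
  seqq <- fixture_tube()
  t <- seqq[[4]]; s <- seqq[[5]]
  w <- inverse_warp(s$frame, t$gt$D, t$K, relative_pose(t, s))
  spot <- (t$gt$spot_mask > 0) | (s$gt$spot_mask > 0)
  err <- apply(abs(w$warped - t$frame$pixels), c(1, 2), mean)
  ok <- w$valid == 1
  nonspec <- mean(err[ok & !dilate_mask(spot, 2)])  # keep clear of spot rims
  spec <- mean(err[ok & spot])
  expect_lt(nonspec, 0.01)
  expect_gt(spec, 5 * nonspec)
})

test_that("crop_resize: identity, shape contract, constant preservation", {
  sq <- random_image(32, 32)
  expect_identical(crop_resize(sq, 32L)$pixels, sq)
  rect <- random_image(30, 40)
  out <- crop_resize(rect, 28L)
  expect_equal(dim(out$pixels), c(28, 28, 3))
  cst <- array(0.37, c(30, 40, 3))
  expect_equal(crop_resize(cst, 16L)$pixels, array(0.37, c(16, 16, 3)),
               tolerance = 1e-12)
})

test_that("undistort: zero coefficients are the identity, barrel lines straighten", {
  img <- random_image(32, 32)
  K0 <- endo_intrinsics(30, 30, 15.5, 15.5, distortion = c(0, 0, 0, 0))
  expect_identical(undistort(img, K0)$pixels, img)
  # synthesize a barrel-distorted view of a smooth grid pattern, then check
  # that undistortion brings it back toward the ideal image
  H <- 64; W <- 64
  K <- endo_intrinsics(40, 40, 31.5, 31.5, distortion = c(-0.25, 0.05, 0, 0))
  uu <- matrix(rep(0:(W - 1), each = H), H, W)
  vv <- matrix(rep(0:(H - 1), times = W), H, W)
  pat <- 0.5 + 0.22 * sin(uu * 0.7) + 0.22 * sin(vv * 0.7)
  lines <- array(rep(pat, 3), c(H, W, 3))
  # distorted image: sample ideal image at undistorted coords (inverse op of
  # undistort), i.e. barrel-bend the lines
  ns <- asNamespace("endodepth")
  dirs <- ns$camera_dirs(H, W, K)
  # invert the radial model numerically per pixel (fixed point)
  xd <- dirs$x; yd <- dirs$y
  x <- xd; y <- yd
  for (i in 1:30) {
    r2 <- x^2 + y^2
    rad <- 1 + K$distortion[1] * r2 + K$distortion[2] * r2^2
    x <- xd / rad; y <- yd / rad
  }
  u <- K$fx * x + K$cx; v <- K$fy * y + K$cy
  bent <- ns$vof(ns$nd_grid_sample(lines, u, v)$out)
  straightened <- undistort(bent, K)$pixels
  # undistortion must bring the bent lines back toward the ideal straight
  # image (compare away from the border where the remap leaves the view)
  inner <- 8:56
  err_bent <- mean(abs(bent[inner, inner, 1] - lines[inner, inner, 1]))
  err_str <- mean(abs(straightened[inner, inner, 1] - lines[inner, inner, 1]))
  expect_lt(err_str, 0.5 * err_bent)
})

test_that("sequence round-trips through the on-disk layout", {
  seqq <- render_sequence(scene_spec(resolution = 32L, n_frames = 3L))
  dir <- file.path(tempdir(), "endodepth-test-seq")
  unlink(dir, recursive = TRUE)
  write_sequence(seqq, dir)
  back <- read_sequence(dir)
  expect_equal(length(back$frames), 3)
  expect_lt(max(abs(back$frames[[2]]$pixels - seqq[[2]]$frame$pixels)), 1 / 255)
  expect_equal(back$K$fx, seqq[[1]]$K$fx)
  expect_lt(max(abs(back$depths[[2]]$values - seqq[[2]]$gt$D$values)), 1e-3)
  expect_equal(back$poses[[2]]$t, seqq[[2]]$pose$t, tolerance = 1e-9)
})

test_that("frame and intrinsics IO round-trip", {
  px <- random_image(16, 16)
  f <- tempfile(fileext = ".png")
  write_frame(px, f)
  back <- read_frame(f)
  expect_lt(max(abs(back$pixels - px)), 1 / 255)
  K <- endo_intrinsics(100, 101, 63.5, 64.2, distortion = c(-0.2, 0.04))
  for (ext in c(".json", ".yaml")) {
    kf <- tempfile(fileext = ext)
    write_intrinsics(K, kf)
    K2 <- read_intrinsics(kf)
    expect_equal(K2$fx, K$fx)
    expect_equal(K2$distortion, K$distortion)
  }
})
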