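# Specular segmentation, inpainting, and the preprocessing cache.

test_that("segmentation: empty on mid-gray, dead zone under small shifts", {
  gray <- array(0.5, c(32, 32, 3))
  expect_equal(length(segment_speculars(gray)$regions), 0)
  set.seed(71)
  dark <- array(runif(32 * 32 * 3, 0.1, 0.3), c(32, 32, 3))
  a <- segment_speculars(dark)
  b <- segment_speculars(pmin(dark + 0.05, 1))
  expect_identical(a$mask, b$mask)  # below all thresholds either way
  expect_equal(sum(a$mask), 0)
})

test_that("detector recovers rendered specular spots (IoU >= 0.9)", {
  fr <- fixture_tube()[[4]]  # reference frame: spots at full strength
  det <- segment_speculars(fr$frame)
  expect_gt(length(det$regions), 0)
  expect_gte(iou_masks(det$mask_raw, fr$gt$spot_mask), 0.9)
  # regions partition the dilated mask and respect min_area
  areas <- vapply(det$regions, `[[`, numeric(1), "area")
  expect_equal(sum(areas), sum(det$mask))
  expect_true(all(areas >= det$params$min_area))
})

test_that("segmentation is monotone in the absolute threshold", {
  fr <- fixture_tube()[[4]]
  prev <- segment_speculars(fr$frame, t_abs = 0.85)$mask
  for (t in c(0.92, 0.97)) {
    cur <- segment_speculars(fr$frame, t_abs = t)$mask
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("inpainting: identity on empty mask, constant fill, maximum principle", {
  set.seed(72)
  I <- random_image(24, 24)
  empty <- matrix(0, 24, 24)
  expect_identical(inpaint_speculars(I, empty)$pixels, I)
  # constant image with a hole stays constant
  C <- array(0.42, c(24, 24, 3))
  hole <- matrix(0, 24, 24); hole[8:14, 9:15] <- 1
  filled <- inpaint_speculars(C, hole)
  expect_equal(filled$pixels, C, tolerance = 1e-6)
  # maximum principle: filled values inside the hole's boundary range
  J <- inpaint_speculars(I, hole, tol = 1e-6, max_iter = 5000)
  ring <- (matrix(0, 24, 24))
  ring[7:15, 8:16] <- 1; ring[8:14, 9:15] <- 0
  for (ch in 1:3) {
    vals <- J$pixels[, , ch][hole == 1]
    bnd <- I[, , ch][ring == 1]
    expect_gte(min(vals), min(bnd) - 1e-4)
    expect_lte(max(vals), max(bnd) + 1e-4)
  }
  # untouched outside the mask
  expect_identical(J$pixels[rep(hole == 0, 3)], I[rep(hole == 0, 3)])
  expect_error(inpaint_speculars(I, matrix(1, 24, 24)), "whole image")
})

test_that("inpainting is idempotent once harmonic", {
  set.seed(73)
  I <- random_image(20, 20)
  hole <- matrix(0, 20, 20); hole[6:10, 6:10] <- 1
  once <- inpaint_speculars(I, hole, tol = 1e-7, max_iter = 20000)
  twice <- inpaint_speculars(once$pixels, hole, tol = 1e-7, max_iter = 20000)
  expect_lt(max(abs(once$pixels - twice$pixels)), 1e-4)
})

test_that("preprocessing moves spotted pixels toward the diffuse image", {
  fr <- fixture_tube()[[4]]
  pp <- preprocess_frame(fr$frame)
  AS <- fr$gt$A * array(fr$gt$S, dim(fr$gt$A))
  spot <- fr$gt$spot_mask > 0
  err_rem <- mean(abs(pp$I_rem$pixels - AS)[rep(spot, 3)])
  err_raw <- mean(abs(fr$frame$pixels - AS)[rep(spot, 3)])
  expect_lt(err_rem, err_raw)
  # unchanged outside the dilated mask
  outside <- pp$M_trad$mask == 0
  expect_identical(pp$I_rem$pixels[rep(outside, 3)],
                   fr$frame$pixels[rep(outside, 3)])
  # spot-free frame passes through untouched
  seq0 <- render_sequence(scene_spec(resolution = 48L, n_frames = 2L,
                                     specular_strength = 0))
  pp0 <- preprocess_frame(seq0[[1]]$frame)
  expect_identical(pp0$I_rem$pixels, seq0[[1]]$frame$pixels)
})

test_that("the preprocessing cache returns identical bytes without recompute", {
  fr <- fixture_tube()[[4]]
  cd <- file.path(tempdir(), "endodepth-test-cache")
  unlink(cd, recursive = TRUE)
  first <- preprocess_frame(fr$frame, cache_dir = cd)
  expect_false(first$from_cache)
  second <- preprocess_frame(fr$frame, cache_dir = cd)
  expect_true(second$from_cache)
  expect_identical(first$I_rem$pixels, second$I_rem$pixels)
  expect_identical(first$M_trad$mask, second$M_trad$mask)
})
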