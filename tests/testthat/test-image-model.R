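# The non-Lambertian image algebra I = A*S + M.

test_that("frame and intrinsics constructors validate their invariants", {
  expect_error(endo_frame(array(1.2, c(4, 4, 3))), "0,1")
  expect_error(endo_frame(array(NaN, c(4, 4, 3))), "finite")
  expect_error(endo_intrinsics(-1, 1, 0, 0), "positive")
  expect_error(endo_intrinsics(10, 10, 99, 5, width = 16, height = 16), "bounds")
  expect_error(depth_map(matrix(0, 2, 2)), "> 0")
  f <- endo_frame(array(0.5, c(6, 8, 3)), frame_id = 3)
  expect_equal(c(f$height, f$width, f$frame_id), c(6, 8, 3))
})

test_that("compose_image handles the Lambertian and pure-specular limits", {
  A <- array(0.5, c(4, 4, 3))
  S1 <- array(1, c(4, 4, 1))
  M0 <- array(0, c(4, 4, 3))
  expect_equal(compose_image(A, S1, M0)$pixels, A)          # I = AS
  I2 <- compose_image(array(0, c(4, 4, 3)), array(0.7, c(4, 4, 1)),
                      array(0.3, c(4, 4, 3)))
  expect_equal(I2$pixels, array(0.3, c(4, 4, 3)))           # I = M
  expect_error(compose_image(A, array(1, c(5, 5, 1)), M0), "shape")
  expect_error(compose_image(A - 1, S1, M0), "nonnegative")
})

test_that("remove_speculars inverts composition and clamps at zero", {
  set.seed(21)
  A <- array(runif(48, 0, 0.7), c(4, 4, 3))
  S <- array(runif(16, 0.2, 1), c(4, 4, 1))
  M <- array(runif(48, 0, 0.2), c(4, 4, 3))
  I <- compose_image(A, S, M)
  AS <- A * array(S, c(4, 4, 3))
  expect_equal(remove_speculars(I, M)$pixels, AS, tolerance = 1e-12)
  expect_equal(remove_speculars(I, array(0, c(4, 4, 3)))$pixels, I$pixels)
  big <- array(2 * I$pixels[1], c(4, 4, 3)) * 0 + 1  # M > I everywhere
  expect_true(all(remove_speculars(I, big)$pixels >= 0))
})

test_that("binarize_residual thresholds on the 8-bit scale", {
  I <- array(0.3, c(5, 5, 3))
  AS <- I
  expect_equal(sum(binarize_residual(I, AS, 50)), 0)        # zero residual
  I51 <- I
  I51[2, 2, ] <- I51[2, 2, ] + 51 / 255                     # residual 51 at one pixel
  m <- binarize_residual(I51, AS, 50)
  expect_equal(sum(m), 1)
  expect_equal(m[2, 2], 1)
  expect_error(binarize_residual(I, AS, 300), "0, 255")
})

test_that("binarize_residual is monotone in the threshold", {
  set.seed(22)
  I <- random_image(12, 12)
  AS <- pmax(I - array(runif(432, 0, 0.5), dim(I)), 0)
  prev <- binarize_residual(I, AS, 10)
  for (t in c(50, 120, 200)) {
    cur <- binarize_residual(I, AS, t)
    expect_true(all(cur <= prev))  # raising threshold shrinks the mask
    prev <- cur
  }
})

test_that("renderer ground truth recomposes to the rendered image", {
  fr <- fixture_tube()[[2]]
  re <- compose_image(fr$gt$A, fr$gt$S, fr$gt$M)
  expect_lt(max(abs(re$pixels - fr$frame$pixels)), 1 / 255)
  # round trip under the algebraic inverse where unclipped
  AS <- fr$gt$A * array(fr$gt$S, dim(fr$gt$A))
  unclipped <- AS + fr$gt$M <= 1
  rem <- remove_speculars(re, fr$gt$M)$pixels
  expect_lt(max(abs((rem - AS) * unclipped)), 1e-6)
})

test_that("decomposition container validates and clips AS", {
  A <- array(0.9, c(4, 4, 3)); S <- array(1.5, c(4, 4, 1)); M <- array(0.1, c(4, 4, 3))
  d <- decomposition(A, S, M)
  expect_equal(max(d$AS), 1)  # 0.9*1.5 clipped
  expect_error(decomposition(A * 2, S, M), "0,1")
  expect_error(decomposition(A, S - 2, M), "nonneg")
})
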