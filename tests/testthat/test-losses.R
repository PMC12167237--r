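# Loss closed forms, limits and reduction semantics.

test_that("SSIM: self-similarity, symmetry, constant closed form", {
  set.seed(51)
  x <- random_image(10, 10)
  expect_equal(ssim_map(x, x), array(1, dim(x)), tolerance = 1e-12)
  y <- random_image(10, 10)
  expect_equal(ssim_map(x, y), ssim_map(y, x), tolerance = 1e-12)
  a <- array(0.2, c(8, 8, 3)); b <- array(0.4, c(8, 8, 3))
  expect_equal(ssim_map(a, b)[4, 4, 1], oracle_ssim_const(0.2, 0.4),
               tolerance = 1e-10)
  expect_error(ssim_map(x, random_image(9, 9)), "shape")
})

test_that("photometric loss: zero on identity, constant closed form, alpha limits", {
  set.seed(52)
  x <- random_image(8, 8)
  expect_lt(max(abs(photometric_loss(x, x))), 1e-12)
  a <- array(0.2, c(8, 8, 3)); b <- array(0.4, c(8, 8, 3))
  expected <- 0.85 * (1 - oracle_ssim_const(0.2, 0.4)) / 2 + 0.15 * 0.2
  expect_equal(photometric_loss(a, b, 0.85)[3, 3, 1], expected, tolerance = 1e-10)
  expect_lt(abs(expected - 0.1150), 1e-4)
  # alpha = 0 reduces to L1; alpha = 1 to SSIM dissimilarity
  y <- random_image(8, 8)
  l1 <- apply(abs(x - y), c(1, 2), mean)
  expect_equal(photometric_loss(x, y, 0)[, , 1], l1, tolerance = 1e-12)
  sd2 <- (1 - apply(ssim_map(x, y), c(1, 2), mean)) / 2
  expect_equal(photometric_loss(x, y, 1)[, , 1], sd2, tolerance = 1e-12)
})

test_that("decomposition loss matches the photometric form and renderer oracle", {
  a <- array(0.2, c(8, 8, 3)); b <- array(0.4, c(8, 8, 3))
  expect_equal(decomposition_loss(a, b), mean(photometric_loss(a, b)),
               tolerance = 1e-12)
  expect_equal(decomposition_loss(a, a), 0, tolerance = 1e-12)
  # spot-free rendered frame: I_rem == I == AS, loss ~ 0
  seqq <- render_sequence(scene_spec(resolution = 64L, n_frames = 2L,
                                     specular_strength = 0))
  fr <- seqq[[1]]
  AS <- fr$gt$A * array(fr$gt$S, dim(fr$gt$A))
  expect_lt(decomposition_loss(AS, fr$frame$pixels), 1e-3)
})

test_that("albedo loss averages over the valid pixels only", {
  A1 <- array(0.3, c(6, 6, 3)); A2 <- array(0.5, c(6, 6, 3))
  expect_equal(albedo_loss(A1, A1), 0)
  expect_equal(albedo_loss(A1, A2), 0.2, tolerance = 1e-12)
  half <- matrix(rep(c(1, 0), 18), 6, 6)
  expect_equal(albedo_loss(A1, A2, half), 0.2, tolerance = 1e-12)
  expect_warning(z <- albedo_loss(A1, A2, half * 0), "empty")
  expect_equal(z, 0)
})

test_that("smoothness loss: zero for constant depth, ramp value, edge damping", {
  Ic <- array(0.5, c(4, 4, 3))
  expect_equal(smoothness_loss(matrix(2, 4, 4), Ic), 0)
  ramp <- matrix(rep(2 * (0:3), each = 4), 4, 4) + 1  # slope 2 along x
  expect_equal(smoothness_loss(ramp, Ic), 2, tolerance = 1e-12)
  # increasing image gradient strictly decreases the loss
  prev <- Inf
  for (g in c(0.1, 0.5, 1)) {
    Ig <- array(rep(seq(0, g, length.out = 4), each = 4), c(4, 4, 3))
    cur <- smoothness_loss(ramp, Ig)
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("masked means ignore the values at masked-out pixels", {
  set.seed(53)
  A1 <- random_image(6, 6); A2 <- random_image(6, 6)
  mu <- matrix(rbinom(36, 1, 0.6), 6, 6)
  base <- albedo_loss(A1, A2, mu)
  A2p <- A2
  A2p[rep(mu == 0, 3)] <- runif(sum(mu == 0) * 3)  # perturb masked pixels
  expect_equal(albedo_loss(A1, A2p, mu), base, tolerance = 1e-12)
})

test_that("total loss assembles the weighted sum", {
  rep0 <- total_loss(0, 0, 0, 0, 0)
  expect_equal(rep0$total, 0)
  rep1 <- total_loss(0.1, 0.1, 0.2, 0.3, 1.0)
  expect_equal(rep1$total, 0.39, tolerance = 1e-12)
  w <- loss_weights()
  expect_equal(c(w$alpha, w$lambda_d, w$lambda_a, w$lambda_r, w$lambda_es),
               c(0.85, 0.2, 0.2, 1, 0.01))
  # map-valued terms are mask-averaged
  lr_map <- matrix(1, 4, 4); lr_map[1, 1] <- 9
  mu <- matrix(1, 4, 4); mu[1, 1] <- 0
  rep2 <- total_loss(0, 0, 0, lr_map, 0, mu = mu)
  expect_equal(rep2$per_term$L_r, 1)
  expect_equal(dim(rep2$per_pixel_r), c(4, 4, 1))
  expect_error(total_loss(NaN, 0, 0, 0, 0), "L_d_t")
})
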