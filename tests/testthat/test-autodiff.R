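# Gradient correctness of the tape engine against central finite
# differences, and tape on/off semantics.

ns <- asNamespace("endodepth")

fd_gradient <- function(param, fwd, all_params, eps = 1e-6) {
  for (p in all_params) p$g <- NULL
  invisible(ns$with_tape({
    l <- fwd()
    ns$ad_backward(l)
    l
  }))
  ga <- param$g
  gn <- array(0, dim(as.array(param$v)))
  for (i in seq_along(param$v)) {
    v0 <- param$v[[i]]
    param$v[[i]] <- v0 + eps
    lp <- ns$vof(fwd())
    param$v[[i]] <- v0 - eps
    lm <- ns$vof(fwd())
    param$v[[i]] <- v0
    gn[[i]] <- (lp - lm) / (2 * eps)
  }
  max(abs(as.numeric(ga) - as.numeric(gn))) / max(1e-8, max(abs(gn)))
}

test_that("elementwise, reduction and shape ops match finite differences", {
  set.seed(11)
  x <- ns$nd_param(array(runif(72, 0.1, 0.9), c(6, 6, 2)))
  s <- ns$nd_param(0.7)
  ps <- list(x, s)
  cases <- list(
    function() ns$nd_mean(ns$nd_abs(ns$nd_sub(ns$nd_exp(x), ns$nd_mul(x, x)))),
    function() ns$nd_sum(ns$nd_div(ns$nd_sigmoid(x), ns$nd_affine(x, 0.5, 1.2))),
    function() ns$nd_mean(ns$nd_min2(ns$nd_softplus(x), ns$nd_elu(ns$nd_neg(x)))),
    function() ns$nd_masked_mean(ns$nd_sqrt(ns$nd_affine(x, 1, 0.5)),
                                 array(rep(c(1, 0), 36), c(6, 6, 2))),
    function() ns$nd_sum(ns$nd_smul(ns$nd_sadd(x, s), s)),
    function() ns$nd_mean(ns$nd_concat_c(list(ns$nd_slice_c(x, 2L),
                                              ns$nd_repc(ns$nd_cmean(x), 3L)))),
    function() ns$nd_mean(ns$nd_clamp(ns$nd_affine(x, 3, -1), 0, 1))
  )
  for (f in cases) expect_lt(fd_gradient(x, f, ps), 1e-5)
  expect_lt(fd_gradient(s, cases[[5]], ps), 1e-6)
})

test_that("conv, pooling, box filter and grid sampling match finite differences", {
  set.seed(12)
  x <- ns$nd_param(array(runif(72), c(6, 6, 2)))
  w <- ns$nd_param(matrix(rnorm(18 * 3, sd = 0.3), 18, 3))
  b <- ns$nd_param(rnorm(3, sd = 0.1))
  src <- ns$nd_param(array(runif(108), c(6, 6, 3)))
  u <- ns$nd_param(matrix(runif(36, 0, 5), 6, 6))
  v <- ns$nd_param(matrix(runif(36, 0, 5), 6, 6))
  ps <- list(x, w, b, src, u, v)
  fconv <- function() ns$nd_mean(ns$nd_abs(ns$nd_conv2d(ns$nd_sigmoid(x), w, b, 3L, 2L, 3L)))
  expect_lt(fd_gradient(x, fconv, ps), 1e-6)
  expect_lt(fd_gradient(w, fconv, ps), 1e-6)
  expect_lt(fd_gradient(b, fconv, ps), 1e-6)
  fpool <- function() ns$nd_mean(ns$nd_upsample2(ns$nd_avgpool2(ns$nd_elu(x))))
  expect_lt(fd_gradient(x, fpool, ps), 1e-6)
  fbox <- function() ns$nd_mean(ns$nd_boxmean3(ns$nd_mul(x, x)))
  expect_lt(fd_gradient(x, fbox, ps), 1e-6)
  fgs <- function() {
    r <- ns$nd_grid_sample(src, u, v)
    ns$nd_mean(ns$nd_abs(r$out))
  }
  expect_lt(fd_gradient(src, fgs, ps), 1e-6)
  expect_lt(fd_gradient(u, fgs, ps, eps = 1e-5), 1e-4)
  expect_lt(fd_gradient(v, fgs, ps, eps = 1e-5), 1e-4)
  fdx <- function() ns$nd_mean(ns$nd_abs(ns$nd_diffx(ns$nd_mul(x, x))))
  fdy <- function() ns$nd_mean(ns$nd_abs(ns$nd_diffy(ns$nd_mul(x, x))))
  expect_lt(fd_gradient(x, fdx, ps), 1e-5)
  expect_lt(fd_gradient(x, fdy, ps), 1e-5)
})

test_that("losses and the pose map are differentiable end to end", {
  set.seed(13)
  a <- ns$nd_param(array(runif(48, 0.2, 0.8), c(4, 4, 3)))
  b <- array(runif(48, 0.2, 0.8), c(4, 4, 3))
  v6 <- ns$nd_param(c(0.05, -0.03, 0.08, 0.01, 0.002, -0.004))
  ps <- list(a, v6)
  floss <- function() ns$nd_mean(ns$nd_photometric(a, b, 0.85))
  expect_lt(fd_gradient(a, floss, ps), 1e-5)
  frot <- function() {
    rt <- ns$nd_pose_to_Rt(v6)
    acc <- rt$t[[1]]
    for (r in rt$R) acc <- ns$nd_add(acc, ns$nd_mul(r, r))
    acc
  }
  expect_lt(fd_gradient(v6, frot, ps), 1e-6)
  # zero rotation branch stays finite
  v0 <- ns$nd_param(rep(0, 6))
  ps0 <- list(v0)
  frot0 <- function() {
    rt <- ns$nd_pose_to_Rt(v0)
    acc <- rt$t[[2]]
    for (r in rt$R) acc <- ns$nd_add(acc, ns$nd_mul(r, r))
    acc
  }
  expect_lt(fd_gradient(v0, frot0, ps0), 1e-5)
})

test_that("ops return plain arrays when the tape is off", {
  x <- array(runif(27), c(3, 3, 3))
  expect_true(is.array(ns$nd_sigmoid(x)))
  expect_false(inherits(ns$nd_mean(x), "nd"))
})
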