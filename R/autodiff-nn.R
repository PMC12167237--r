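# Structured ops for H x W x C arrays: same-padding convolution (im2col +
# BLAS matmul), 2x average pooling, nearest-neighbour upsampling, 3x3 box
# filtering with reflection padding, and differentiable bilinear grid
# sampling. Index maps are cached per shape.

.idxcache <- new.env(parent = emptyenv())

# spatially-flipped, channel-transposed weights: correlation adjoint
flip_weights <- function(vw, k, cin, cout) {
  arr <- array(vw, dim = c(k, k, cin, cout))
  arr <- arr[k:1, k:1, , , drop = FALSE]
  matrix(aperm(arr, c(1, 2, 4, 3)), k * k * cout, cin)
}

# raw same-padding correlation (no tape): H x W x Cin -> H x W x Cout
conv2d_raw <- function(vx, vw, k, cin, cout) {
  d <- dim(vx)
  H <- d[1]; W <- d[2]
  col <- im2col_pad(vx, H, W, cin, k)
  y <- col %*% vw
  dim(y) <- c(H, W, cout)
  list(y = y, col = col)
}

#' Same-padding 2-D convolution (odd kernel, stride 1)
#'
#' `w` is a (k*k*cin) x cout weight matrix, `b` a length-cout bias; both may
#' be parameter nodes. The input gradient is computed as a transposed
#' convolution (flipped kernel), keeping the backward pass in BLAS.
#' @keywords internal
nd_conv2d <- function(x, w, b, k, cin, cout) {
  vx <- vof(x); vw <- vof(w); vb <- vof(b)
  d <- dim(vx)
  H <- d[1]; W <- d[2]
  stopifnot(d[3] == cin)
  fwd <- conv2d_raw(vx, vw, k, cin, cout)
  y <- fwd$y
  for (cc in seq_len(cout)) y[, , cc] <- y[, , cc] + vb[cc]
  col <- fwd$col
  mkop(y, list(x, w, b), function(g) {
    gm <- g
    dim(gm) <- c(H * W, cout)
    acc_grad(w, crossprod(col, gm))
    acc_grad(b, colSums(gm))
    if (nd_requires(x)) {
      dim(g) <- c(H, W, cout)
      wt <- flip_weights(vw, k, cin, cout)
      acc_grad(x, conv2d_raw(g, wt, k, cout, cin)$y)
    }
  })
}

#' 2x2 average pooling (even H, W)
#' @keywords internal
nd_avgpool2 <- function(x) {
  vx <- vof(x)
  d <- dim(vx)
  H <- d[1]; W <- d[2]; C <- d[3]
  o1 <- seq(1L, H, 2L); o2 <- seq(2L, H, 2L)
  p1 <- seq(1L, W, 2L); p2 <- seq(2L, W, 2L)
  y <- (vx[o1, p1, , drop = FALSE] + vx[o2, p1, , drop = FALSE] +
        vx[o1, p2, , drop = FALSE] + vx[o2, p2, , drop = FALSE]) / 4
  mkop(y, list(x), function(g) {
    gx <- array(0, dim = d)
    gq <- g / 4
    gx[o1, p1, ] <- gq
    gx[o2, p1, ] <- gq
    gx[o1, p2, ] <- gq
    gx[o2, p2, ] <- gq
    acc_grad(x, gx)
  })
}

#' Nearest-neighbour 2x upsampling
#' @keywords internal
nd_upsample2 <- function(x) {
  vx <- vof(x)
  d <- dim(vx)
  ri <- rep(seq_len(d[1]), each = 2L)
  rj <- rep(seq_len(d[2]), each = 2L)
  y <- vx[ri, rj, , drop = FALSE]
  mkop(y, list(x), function(g) {
    H2 <- 2L * d[1]; W2 <- 2L * d[2]
    o1 <- seq(1L, H2, 2L); o2 <- seq(2L, H2, 2L)
    p1 <- seq(1L, W2, 2L); p2 <- seq(2L, W2, 2L)
    acc_grad(x, g[o1, p1, , drop = FALSE] + g[o2, p1, , drop = FALSE] +
                g[o1, p2, , drop = FALSE] + g[o2, p2, , drop = FALSE])
  })
}

#' Flatten H x W x C to a 1 x (H*W*C) row matrix (column-major)
#' @keywords internal
nd_flatten <- function(x) {
  vx <- vof(x)
  d <- dim(vx)
  y <- matrix(vx, 1L)
  mkop(y, list(x), function(g) {
    dim(g) <- d
    acc_grad(x, g)
  })
}

#' Spatial mean: H x W x C -> 1 x C matrix
#' @keywords internal
nd_spatial_mean <- function(x) {
  vx <- vof(x)
  d <- dim(vx)
  N <- d[1] * d[2]
  m <- vx
  dim(m) <- c(N, d[3])
  y <- matrix(colSums(m) / N, 1L, d[3])
  mkop(y, list(x), function(g) {
    acc_grad(x, array(rep(as.numeric(g), each = N) / N, dim = d))
  })
}

#' 3x3 mean filter with reflection padding, per channel (separable)
#' @keywords internal
nd_boxmean3 <- function(x) {
  vx <- vof(x)
  d <- dim(vx)
  y <- box3_fwd(vx, d[1], d[2], d[3])
  dim(y) <- d
  mkop(y, list(x), function(g) {
    gx <- box3_adj(g, d[1], d[2], d[3])
    dim(gx) <- d
    acc_grad(x, gx)
  })
}

#' Forward differences along columns (x) and rows (y)
#'
#' `nd_diffx` returns `x[, 2:W, ] - x[, 1:(W-1), ]` (H x (W-1) x C);
#' `nd_diffy` the row analogue.
#' @keywords internal
nd_diffx <- function(x) {
  vx <- vof(x)
  d <- dim(vx)
  W <- d[2]
  y <- vx[, 2:W, , drop = FALSE] - vx[, 1:(W - 1L), , drop = FALSE]
  mkop(y, list(x), function(g) {
    gx <- array(0, dim = d)
    gx[, 2:W, ] <- gx[, 2:W, , drop = FALSE] + g
    gx[, 1:(W - 1L), ] <- gx[, 1:(W - 1L), , drop = FALSE] - g
    acc_grad(x, gx)
  })
}

#' @rdname nd_diffx
#' @keywords internal
nd_diffy <- function(x) {
  vx <- vof(x)
  d <- dim(vx)
  H <- d[1]
  y <- vx[2:H, , , drop = FALSE] - vx[1:(H - 1L), , , drop = FALSE]
  mkop(y, list(x), function(g) {
    gx <- array(0, dim = d)
    gx[2:H, , ] <- gx[2:H, , , drop = FALSE] + g
    gx[1:(H - 1L), , ] <- gx[1:(H - 1L), , , drop = FALSE] - g
    acc_grad(x, gx)
  })
}

#' Differentiable bilinear sampling with zero padding
#'
#' Samples `src` (H x W x C) at continuous 0-based pixel coordinates
#' (`u` = column, `v` = row), each H x W. Returns `list(out=, valid=)` where
#' `valid` marks samples whose 2x2 support lies fully inside the source and
#' which pass the caller-supplied `extra_valid` gate (e.g. positive depth
#' after the rigid transform). Invalid samples are zero. Gradients flow to
#' `src`, `u` and `v`.
#' @keywords internal
nd_grid_sample <- function(src, u, v, extra_valid = NULL) {
  vs <- vof(src)
  vu <- vof(u); vv <- vof(v)
  uvdim <- dim(vu)
  HO <- uvdim[1]; WO <- uvdim[2]
  d <- dim(vs)
  H <- d[1]; W <- d[2]; C <- d[3]
  ev <- if (is.null(extra_valid)) NULL else as.numeric(extra_valid) * 1
  fw <- gridsample_fwd(vs, H, W, C, as.numeric(vu), as.numeric(vv), HO, WO, ev)
  out <- fw$out
  dim(out) <- c(HO, WO, C)
  valid <- matrix(fw$valid, HO, WO)
  node <- mkop(out, list(src, u, v), function(g) {
    need_src <- nd_requires(src)
    need_uv <- nd_requires(u) || nd_requires(v)
    bw <- gridsample_bwd(vs, H, W, C, as.numeric(vu), as.numeric(vv), HO, WO,
                         fw$valid, as.numeric(g), need_src, need_uv)
    if (need_src) {
      gs <- bw$gsrc
      dim(gs) <- d
      acc_grad(src, gs)
    }
    if (need_uv) {
      gu <- bw$gu; gv <- bw$gv
      dim(gu) <- uvdim; dim(gv) <- uvdim
      acc_grad(u, gu)
      acc_grad(v, gv)
    }
  })
  list(out = node, valid = valid)
}
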