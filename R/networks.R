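# Network contracts: a U-shaped encoder-decoder for depth (disparity in
# (0,1)) and for intrinsic decomposition (albedo via sigmoid, shading via
# softplus), and a convolutional pose regressor emitting an axis-angle +
# translation 6-vector. Architectures are deliberately small and fully
# configurable; the `tiny` preset trains on a CPU.

conv_init <- function(k, cin, cout, bias = 0) {
  n <- k * k * cin
  w <- matrix(stats::rnorm(n * cout, sd = sqrt(2 / n)), n, cout)
  b <- rep(bias, length.out = cout)
  list(w = nd_param(w), b = nd_param(b), k = as.integer(k),
       cin = as.integer(cin), cout = as.integer(cout))
}

conv_apply <- function(layer, x) {
  nd_conv2d(x, layer$w, layer$b, layer$k, layer$cin, layer$cout)
}

preset_widths <- function(preset) {
  switch(preset,
         tiny = c(8L, 16L, 24L),
         small = c(16L, 32L, 64L),
         stop("unknown preset: ", preset))
}

unet_new <- function(cin, cout, widths, out_bias = 0) {
  w <- widths
  list(kind = "unet", cin = cin, cout = cout, widths = w,
       enc1 = conv_init(3, cin, w[1]),
       enc2 = conv_init(3, w[1], w[2]),
       enc3 = conv_init(3, w[2], w[3]),
       dec2 = conv_init(3, w[3] + w[2], w[2]),
       dec1 = conv_init(3, w[2] + w[1], w[1]),
       out = conv_init(3, w[1], cout, bias = out_bias))
}

unet_forward <- function(net, x) {
  e1 <- nd_elu(conv_apply(net$enc1, x))
  e2 <- nd_elu(conv_apply(net$enc2, nd_avgpool2(e1)))
  e3 <- nd_elu(conv_apply(net$enc3, nd_avgpool2(e2)))
  d2 <- nd_elu(conv_apply(net$dec2, nd_concat_c(list(nd_upsample2(e3), e2))))
  d1 <- nd_elu(conv_apply(net$dec1, nd_concat_c(list(nd_upsample2(d2), e1))))
  conv_apply(net$out, d1)
}

# Pose regression works on a fixed 64 x 64 internal resolution (pose is a
# global quantity; resizing is harmless and keeps the flattened feature size
# resolution-independent). Four conv+pool stages bring 64 -> 4, and the
# 4 x 4 map is flattened — not averaged — so the spatial arrangement of
# the features (the optical flow pattern) survives into the regression.
posenet_new <- function(cin, widths) {
  w <- widths
  nf <- 16L * w[3]  # 4*4 spatial positions
  list(kind = "pose", cin = cin, widths = w,
       c1 = conv_init(3, cin, w[1]),
       c2 = conv_init(3, w[1], w[2]),
       c3 = conv_init(3, w[2], w[3]),
       c4 = conv_init(3, w[3], w[3]),
       fc_w = nd_param(matrix(stats::rnorm(nf * 6, sd = sqrt(1 / nf)), nf, 6)),
       fc_b = nd_param(rep(0, 6)))
}

# differentiable bilinear resize to size x size (exact identity if equal)
nd_resize <- function(x, size) {
  d <- dim(vof(x))
  if (d[1] == size && d[2] == size) return(x)
  u <- matrix(rep((seq_len(size) - 0.5) * d[2] / size - 0.5, each = size), size, size)
  v <- matrix(rep((seq_len(size) - 0.5) * d[1] / size - 0.5, times = size), size, size)
  u <- pmin(pmax(u, 0), d[2] - 1)
  v <- pmin(pmax(v, 0), d[1] - 1)
  nd_grid_sample(x, u, v)$out
}

posenet_forward <- function(net, x) {
  h <- nd_resize(x, 64L)
  h <- nd_elu(conv_apply(net$c1, h))
  h <- nd_elu(conv_apply(net$c2, nd_avgpool2(h)))
  h <- nd_elu(conv_apply(net$c3, nd_avgpool2(h)))
  h <- nd_elu(conv_apply(net$c4, nd_avgpool2(h)))
  h <- nd_avgpool2(h)                           # 4 x 4 x w3
  v <- nd_addbias(nd_matmul(nd_flatten(h), net$fc_w), net$fc_b)
  nd_affine(v, 0.01)                            # small initial motions
}

net_params <- function(x) {
  out <- list()
  walk <- function(o) {
    if (is_nd(o)) {
      out[[length(out) + 1L]] <<- o
    } else if (is.list(o)) {
      for (el in o) walk(el)
    }
  }
  walk(x)
  out
}

#' Create the three-network bundle
#'
#' `depth`: image -> disparity in (0,1) (sigmoid U-net);
#' `decompose`: image -> albedo (sigmoid, 3 channels) and shading
#' (softplus, 1 channel); `pose`: channel-stacked image pair -> axis-angle +
#' translation 6-vector. Weight initialization is a pure function of `seed`.
#'
#' @param preset `"tiny"` (CPU tests) or `"small"`.
#' @param seed integer seed for weight initialization.
#' @return object of class `endo_networks`.
#' @export
endo_networks <- function(preset = "tiny", seed = 42L) {
  widths <- preset_widths(preset)
  set.seed(seed)
  nets <- list(
    depth = unet_new(3L, 1L, widths),
    # shading bias ~ softplus^-1(1) so A*S starts near mid-gray
    decompose = unet_new(3L, 4L, widths, out_bias = c(0, 0, 0, 0.5413)),
    pose = posenet_new(6L, widths),
    preset = preset, seed = as.integer(seed)
  )
  structure(nets, class = "endo_networks")
}

#' @export
print.endo_networks <- function(x, ...) {
  np <- sum(vapply(net_params(x), function(p) length(p$v), numeric(1)))
  cat(sprintf("<endo_networks preset=%s, %d parameters, seed=%d>\n",
              x$preset, np, x$seed))
  invisible(x)
}

# forward passes shared by training and inference -------------------------

depth_forward <- function(nets, x, d_min, d_max) {
  disp <- nd_sigmoid(unet_forward(nets$depth, x))
  disparity_to_depth(disp, d_min, d_max)
}

decompose_forward <- function(nets, x) {
  y <- unet_forward(nets$decompose, x)
  list(A = nd_sigmoid(nd_slice_c(y, 1:3)),
       S = nd_softplus(nd_slice_c(y, 4L)))
}

pose_forward <- function(nets, target_px, source_px) {
  posenet_forward(nets$pose, nd_concat_c(list(target_px, source_px)))
}

#' Convert network disparity to metric depth
#'
#' Affine-in-inverse-depth map: `1/D = 1/d_max + disp * (1/d_min - 1/d_max)`
#' so `disp = 1` gives `d_min`, `disp = 0` gives `d_max`, and depth is
#' strictly decreasing in disparity.
#'
#' @param disp disparity array/node with values in `[0, 1]`.
#' @param d_min,d_max depth range bounds, `0 < d_min < d_max`.
#' @return depth array (or node) of the same shape.
#' @export
disparity_to_depth <- function(disp, d_min = 0.1, d_max = 10) {
  if (!(d_min > 0 && d_min < d_max)) stop("need 0 < d_min < d_max")
  a <- 1 / d_min - 1 / d_max
  b <- 1 / d_max
  nd_div(1, nd_affine(disp, a, b))
}
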