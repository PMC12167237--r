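# Differentiable view synthesis: back-project target pixels with their
# depth, move them through the relative camera motion, project into the
# source view (p_s ~ K T D K^-1 p_t), and sample the source bilinearly.
#
# Coordinate convention: 0-based, (0,0) at the centre of the top-left pixel;
# `u` indexes columns, `v` rows. A continuous coordinate u is interpolated
# between columns floor(u) and floor(u)+1.

.dircache <- new.env(parent = emptyenv())

# normalized camera-ray components (K^-1 p) for every pixel; cached per (H,W,K)
camera_dirs <- function(H, W, K) {
  key <- paste("d", H, W, K$fx, K$fy, K$cx, K$cy, sep = "_")
  got <- .dircache[[key]]
  if (!is.null(got)) return(got)
  u <- matrix(rep(0:(W - 1), each = H), H, W)
  v <- matrix(rep(0:(H - 1), times = W), H, W)
  out <- list(x = (u - K$cx) / K$fx, y = (v - K$cy) / K$fy, u = u, v = v)
  .dircache[[key]] <- out
  out
}

#' Reproject target pixels into a source view
#'
#' Back-projects every target pixel with its metric depth, applies the rigid
#' transform `T` (target camera to source camera), and projects with `K`.
#' Points that land behind the source camera are flagged invalid rather than
#' raising an error.
#'
#' @param depth `endo_depth` or H x W matrix of positive depths.
#' @param K `endo_intrinsics`.
#' @param tf `endo_transform` mapping target- to source-camera coordinates.
#' @return list with H x W matrices `u`, `v` (continuous 0-based source
#'   coordinates, possibly out of bounds), `z` (depth in the source camera)
#'   and `valid` (`z > 0`).
#' @export
reproject_pixels <- function(depth, K, tf) {
  D <- depth_values(depth)
  if (any(D <= 0) || !all(is.finite(D))) stop("depth must be positive and finite")
  H <- nrow(D); W <- ncol(D)
  dirs <- camera_dirs(H, W, K)
  if (all(tf$R == diag(3)) && all(tf$t == 0)) {
    # exact identity: integral coordinates, no round-trip rounding
    return(list(u = dirs$u, v = dirs$v, z = D,
                valid = matrix(TRUE, H, W)))
  }
  X <- D * dirs$x
  Y <- D * dirs$y
  Z <- D
  R <- tf$R; t <- tf$t
  Xs <- R[1, 1] * X + R[1, 2] * Y + R[1, 3] * Z + t[1]
  Ys <- R[2, 1] * X + R[2, 2] * Y + R[2, 3] * Z + t[2]
  Zs <- R[3, 1] * X + R[3, 2] * Y + R[3, 3] * Z + t[3]
  valid <- Zs > 1e-8
  Zsafe <- pmax(Zs, 1e-8)
  us <- K$fx * Xs / Zsafe + K$cx
  vs <- K$fy * Ys / Zsafe + K$cy
  us[!valid] <- NA_real_
  vs[!valid] <- NA_real_
  list(u = us, v = vs, z = Zs, valid = valid)
}

#' Inverse-warp a source image into the target view
#'
#' Samples the source image at the coordinates returned by
#' [reproject_pixels()] with bilinear interpolation and zero padding.
#' Validity requires the full 2 x 2 interpolation support inside the source
#' image and a positive transformed depth. With the identity transform the
#' sample coordinates are integral and the warp reproduces the source
#' exactly.
#'
#' @param source `endo_frame` or H x W x C array (the source view).
#' @param depth target-view depth (`endo_depth` or matrix).
#' @param K `endo_intrinsics`.
#' @param tf `endo_transform` (target to source).
#' @return object of class `endo_warp`: list with `warped` (H x W x C,
#'   zeros where invalid) and `valid` (H x W 0/1 matrix).
#' @export
inverse_warp <- function(source, depth, K, tf) {
  px <- frame_pixels(source)
  D <- depth_values(depth)
  if (!all(dim(px)[1:2] == dim(D))) stop("source and depth are not spatially compatible")
  rp <- reproject_pixels(D, K, tf)
  gs <- nd_grid_sample(px, rp$u, rp$v, extra_valid = rp$valid)
  valid <- gs$valid
  dim(valid) <- dim(D)
  structure(list(warped = vof(gs$out), valid = valid), class = "endo_warp")
}

#' @export
print.endo_warp <- function(x, ...) {
  cat(sprintf("<endo_warp %d x %d x %d, %.1f%% valid>\n",
              dim(x$warped)[1], dim(x$warped)[2], dim(x$warped)[3],
              100 * mean(x$valid)))
  invisible(x)
}

# Differentiable warp for training. `src` H x W x C (node or array), `D`
# H x W x 1 depth node, `Rt` from nd_pose_to_Rt (scalar nodes, row-major R).
# Returns list(out = node, valid = plain H x W matrix).
nd_inverse_warp <- function(src, D, K, Rt) {
  d <- dim(vof(D))
  H <- d[1]; W <- d[2]
  dirs <- camera_dirs(H, W, K)
  dx <- array(dirs$x, c(H, W, 1)); dy <- array(dirs$y, c(H, W, 1))
  X <- nd_mul(D, dx)
  Y <- nd_mul(D, dy)
  R <- Rt$R; t <- Rt$t
  Xs <- nd_sadd(nd_add(nd_add(nd_smul(X, R[[1]]), nd_smul(Y, R[[2]])), nd_smul(D, R[[3]])), t[[1]])
  Ys <- nd_sadd(nd_add(nd_add(nd_smul(X, R[[4]]), nd_smul(Y, R[[5]])), nd_smul(D, R[[6]])), t[[2]])
  Zs <- nd_sadd(nd_add(nd_add(nd_smul(X, R[[7]]), nd_smul(Y, R[[8]])), nd_smul(D, R[[9]])), t[[3]])
  zval <- vof(Zs) > 1e-8
  Zsafe <- nd_clamp(Zs, 1e-8, Inf)
  us <- nd_affine(nd_div(Xs, Zsafe), K$fx, K$cx)
  vs <- nd_affine(nd_div(Ys, Zsafe), K$fy, K$cy)
  gs <- nd_grid_sample(src, us, vs, extra_valid = zval)
  valid <- gs$valid
  dim(valid) <- c(H, W)
  list(out = gs$out, valid = valid)
}
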