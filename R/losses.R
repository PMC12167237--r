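# Training objectives. Every loss is written in tape ops, so the same code
# is differentiable inside the training loop and plain array arithmetic when
# called on numeric inputs.
#
# The photometric form throughout is alpha*(1 - SSIM)/2 + (1 - alpha)*L1
# with alpha = 0.85; SSIM uses 3x3 mean-filter windows with reflection
# padding and C1 = 0.01^2, C2 = 0.03^2 (the Monodepth2 convention).

.ssim_c1 <- 0.01^2
.ssim_c2 <- 0.03^2

# tape-level SSIM map (H x W x C in [-1, 1])
nd_ssim <- function(x, y) {
  mx <- nd_boxmean3(x)
  my <- nd_boxmean3(y)
  mxy <- nd_mul(mx, my)
  mx2 <- nd_mul(mx, mx)
  my2 <- nd_mul(my, my)
  sx <- nd_sub(nd_boxmean3(nd_mul(x, x)), mx2)
  sy <- nd_sub(nd_boxmean3(nd_mul(y, y)), my2)
  sxy <- nd_sub(nd_boxmean3(nd_mul(x, y)), mxy)
  num <- nd_mul(nd_affine(mxy, 2, .ssim_c1), nd_affine(sxy, 2, .ssim_c2))
  den <- nd_mul(nd_affine(nd_add(mx2, my2), 1, .ssim_c1),
                nd_affine(nd_add(sx, sy), 1, .ssim_c2))
  nd_div(num, den)
}

# tape-level per-pixel photometric map (H x W x 1):
# alpha*(1 - mean_c SSIM)/2 + (1-alpha)*mean_c |a-b|
nd_photometric <- function(a, b, alpha = 0.85) {
  s <- nd_cmean(nd_ssim(a, b))
  l1 <- nd_cmean(nd_abs(nd_sub(a, b)))
  nd_add(nd_affine(s, -alpha / 2, alpha / 2), nd_affine(l1, 1 - alpha))
}

check_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("inputs must have identical shapes")
}

#' Local structural similarity map
#'
#' SSIM computed in 3x3 mean-filter windows with reflection padding and
#' stabilizers C1 = 0.01^2, C2 = 0.03^2; values lie in `[-1, 1]` and equal 1
#' for identical inputs.
#'
#' @param x,y frames or H x W x C arrays with values in `[0,1]`.
#' @return H x W x C similarity array.
#' @export
ssim_map <- function(x, y) {
  a <- frame_pixels(x); b <- frame_pixels(y)
  check_same_shape(a, b)
  vof(nd_ssim(a, b))
}

#' Per-pixel photometric (reprojection) loss map
#'
#' The alpha-weighted mix of SSIM dissimilarity and L1 used by every
#' image-comparison term; channels are averaged, so the result is one value
#' per pixel. Reduction to a scalar happens only after masking.
#'
#' @param a,b frames or H x W x C arrays.
#' @param alpha SSIM share, default 0.85.
#' @return H x W x 1 loss array (>= 0 up to SSIM stabilizer effects).
#' @export
photometric_loss <- function(a, b, alpha = 0.85) {
  pa <- frame_pixels(a); pb <- frame_pixels(b)
  check_same_shape(pa, pb)
  stopifnot(alpha >= 0, alpha <= 1)
  vof(nd_photometric(pa, pb, alpha))
}

#' Decomposition loss: diffuse reconstruction vs specular-free image
#'
#' Mean over pixels of the photometric map between `AS` and `I_rem`,
#' unmasked. Applied to both the target and each source frame in the total
#' objective.
#'
#' @param AS diffuse reconstruction (frame or array).
#' @param I_rem specular-removed image (frame or array).
#' @param alpha SSIM share, default 0.85.
#' @return scalar loss.
#' @export
decomposition_loss <- function(AS, I_rem, alpha = 0.85) {
  a <- frame_pixels(AS); b <- frame_pixels(I_rem)
  check_same_shape(a, b)
  vof(nd_mean(nd_photometric(a, b, alpha)))
}

#' Albedo consistency loss
#'
#' Mean L1 between the target albedo and the source albedo warped into the
#' target view, over the pixels where the mask is 1. The albedo of a surface
#' point should be viewpoint-independent, so any difference must come from
#' warping error. An all-zero mask yields 0 with a warning.
#'
#' @param A_t target albedo (H x W x 3).
#' @param A_swarped source albedo warped to the target view.
#' @param mu binary H x W mask (1 = use pixel); `NULL` means all ones.
#' @return scalar loss.
#' @export
albedo_loss <- function(A_t, A_swarped, mu = NULL) {
  a <- frame_pixels(A_t); b <- frame_pixels(A_swarped)
  check_same_shape(a, b)
  l1 <- nd_cmean(nd_abs(nd_sub(a, b)))
  if (is.null(mu)) return(vof(nd_mean(l1)))
  mu <- as.matrix(mu)
  if (sum(mu) == 0) {
    warning("albedo_loss: empty mask, returning 0")
    return(0)
  }
  vof(nd_masked_mean(l1, array(mu, dim = c(nrow(mu), ncol(mu), 1))))
}

# tape-level edge-aware smoothness: D, img are H x W x 1 / H x W x C
nd_smoothness <- function(D, img) {
  wx <- exp(-abs(vof(nd_cmean(nd_diffx(vof(img))))))
  wy <- exp(-abs(vof(nd_cmean(nd_diffy(vof(img))))))
  nd_add(nd_mean(nd_mul(nd_abs(nd_diffx(D)), wx)),
         nd_mean(nd_mul(nd_abs(nd_diffy(D)), wy)))
}

#' Edge-aware depth smoothness loss
#'
#' `mean |dx D| exp(-|dx I|) + mean |dy D| exp(-|dy I|)` with forward
#' differences (the last column/row drops out of each term) and the image
#' gradient magnitude averaged over channels. Depth is penalized for varying
#' where the image is flat, but free to change across image edges.
#'
#' @param depth `endo_depth` or H x W matrix.
#' @param image frame or H x W x C array.
#' @return scalar loss (0 for constant depth).
#' @export
smoothness_loss <- function(depth, image) {
  D <- depth_values(depth)
  img <- frame_pixels(image)
  if (!all(dim(D) == dim(img)[1:2])) stop("depth and image sizes disagree")
  vof(nd_smoothness(array(D, c(nrow(D), ncol(D), 1)), img))
}

#' Assemble the total training objective
#'
#' `L = lambda_d (L_d_t + L_d_s) + lambda_a <L_a>_mu + lambda_r <L_r>_mu +
#' lambda_es L_es` where `<.>_mu` is the mean over mask-1 pixels. `L_a` and
#' `L_r` may be passed as per-pixel maps (masked-mean is applied) or as
#' already-reduced scalars.
#'
#' @param L_d_t,L_d_s scalar decomposition losses (target / source side).
#' @param L_a albedo term: scalar or H x W (x 1) map.
#' @param L_r reprojection term: scalar or H x W (x 1) map.
#' @param L_es scalar smoothness loss.
#' @param weights `endo_loss_weights`.
#' @param mu binary H x W mask applied to map-valued `L_a` / `L_r`.
#' @return object of class `endo_loss_report`: list with `total`, `per_term`
#'   (named scalars) and `per_pixel_r` (the unmasked `L_r` map if one was
#'   given, else `NULL`).
#' @export
total_loss <- function(L_d_t, L_d_s, L_a, L_r, L_es,
                       weights = loss_weights(), mu = NULL) {
  red <- function(x) {
    if (length(x) == 1L) return(as.numeric(x))
    x <- as_pixels(as.array(x))
    if (is.null(mu)) return(mean(x))
    m <- sum(mu)
    if (m == 0) {
      warning("total_loss: empty mask, masked term set to 0")
      return(0)
    }
    sum(x * array(as.matrix(mu), dim = dim(x))) / m
  }
  per_pixel_r <- if (length(L_r) > 1L) as_pixels(as.array(L_r)) else NULL
  terms <- c(L_d_t = as.numeric(L_d_t), L_d_s = as.numeric(L_d_s),
             L_a = red(L_a), L_r = red(L_r), L_es = as.numeric(L_es))
  if (!all(is.finite(terms))) {
    stop("non-finite loss term(s): ",
         paste(names(terms)[!is.finite(terms)], collapse = ", "))
  }
  total <- weights$lambda_d * (terms[["L_d_t"]] + terms[["L_d_s"]]) +
    weights$lambda_a * terms[["L_a"]] +
    weights$lambda_r * terms[["L_r"]] +
    weights$lambda_es * terms[["L_es"]]
  structure(list(total = total, per_term = as.list(terms),
                 per_pixel_r = per_pixel_r),
            class = "endo_loss_report")
}

#' @export
print.endo_loss_report <- function(x, ...) {
  cat(sprintf("<endo_loss_report total=%.6f | %s>\n", x$total,
              paste(sprintf("%s=%.4f", names(x$per_term),
                            unlist(x$per_term)), collapse = " ")))
  invisible(x)
}
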