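# The non-Lambertian image model I = A*S + M: an image is albedo times
# shading plus an additive specular component. Saturated highlights on wet
# tissue are treated as their own light component rather than being absorbed
# into albedo or shading.

# broadcast an H x W x 1 map over k channels (plain arrays)
bc_channels <- function(x, k) {
  d <- dim(x)
  if (d[3] == k) return(x)
  stopifnot(d[3] == 1L)
  array(x, dim = c(d[1], d[2], k))
}

#' Loss weights for the training objective
#'
#' Defaults: `alpha = 0.85` (SSIM share of the photometric loss) and term
#' weights `lambda_d = 0.2`, `lambda_a = 0.2`, `lambda_r = 1`,
#' `lambda_es = 0.01`.
#'
#' @param alpha SSIM/L1 mixing factor in `[0,1]`.
#' @param lambda_d,lambda_a,lambda_r,lambda_es nonnegative term weights for
#'   the decomposition, albedo, reprojection and edge-aware smoothness terms.
#' @return object of class `endo_loss_weights`.
#' @export
loss_weights <- function(alpha = 0.85, lambda_d = 0.2, lambda_a = 0.2,
                         lambda_r = 1, lambda_es = 0.01) {
  stopifnot(alpha >= 0, alpha <= 1, lambda_d >= 0, lambda_a >= 0,
            lambda_r >= 0, lambda_es >= 0)
  structure(list(alpha = alpha, lambda_d = lambda_d, lambda_a = lambda_a,
                 lambda_r = lambda_r, lambda_es = lambda_es),
            class = "endo_loss_weights")
}

#' Bundle an intrinsic decomposition (A, S, M)
#'
#' Validates the component ranges and stores the diffuse reconstruction
#' `AS = clip(A * S, 0, 1)` alongside.
#'
#' @param A albedo, H x W x 3 in `[0,1]`.
#' @param S shading, H x W x 1 (or matrix), nonnegative.
#' @param M specular component, H x W x 3 (or x 1), nonnegative.
#' @return object of class `endo_decomposition` with fields `A`, `S`, `M`,
#'   `AS`.
#' @export
decomposition <- function(A, S, M) {
  A <- as_pixels(A); S <- as_pixels(S); M <- as_pixels(M)
  if (min(A) < 0 || max(A) > 1) stop("albedo must lie in [0,1]")
  if (min(S) < 0) stop("shading must be nonnegative")
  if (min(M) < 0) stop("specular component must be nonnegative")
  k <- dim(A)[3]
  AS <- pmin(pmax(A * bc_channels(S, k), 0), 1)
  dim(AS) <- dim(A)
  structure(list(A = A, S = S, M = bc_channels(M, k), AS = AS),
            class = "endo_decomposition")
}

#' @export
print.endo_decomposition <- function(x, ...) {
  cat(sprintf("<endo_decomposition %d x %d: S in [%.3f, %.3f], specular cover %.1f%%>\n",
              dim(x$A)[1], dim(x$A)[2], min(x$S), max(x$S),
              100 * mean(apply(x$M, c(1, 2), max) > 0.05)))
  invisible(x)
}

#' Compose an image from albedo, shading and speculars
#'
#' Implements `I = clip(A * S + M, 0, 1)`; a single-channel shading map is
#' broadcast over the albedo channels.
#'
#' @param A albedo array H x W x 3 (values >= 0).
#' @param S shading array H x W x 1 or matrix (values >= 0).
#' @param M specular array, same spatial size (values >= 0).
#' @return an `endo_frame` with the composed image.
#' @export
compose_image <- function(A, S, M) {
  A <- as_pixels(A); S <- as_pixels(S); M <- as_pixels(M)
  k <- dim(A)[3]
  S <- bc_channels(S, k)
  M <- bc_channels(M, k)
  if (!all(dim(A)[1:2] == dim(S)[1:2]) || !all(dim(A) == dim(M))) {
    stop("component shapes do not agree")
  }
  if (min(A) < 0 || min(S) < 0 || min(M) < 0) {
    stop("components must be nonnegative")
  }
  endo_frame(pmin(pmax(A * S + M, 0), 1))
}

#' Subtract the specular component from an image
#'
#' The algebraic removal `max(I - M, 0)`. In training, the practical
#' specular-free target comes from segmentation + inpainting
#' ([preprocess_frame()]); this is the exact inverse used when `M` is known.
#'
#' @param I `endo_frame` or pixel array.
#' @param M specular array (H x W x 3 or x 1).
#' @return `endo_frame` with `max(I - M, 0)`.
#' @export
remove_speculars <- function(I, M) {
  px <- frame_pixels(I)
  M <- bc_channels(as_pixels(M), dim(px)[3])
  if (!all(dim(px) == dim(M))) stop("shape mismatch between image and M")
  endo_frame(pmax(px - M, 0))
}

#' Write / read a decomposition
#'
#' Writes `A`, `S` (clipped to `[0,1]`) and `M` as 8-bit PNGs under
#' `prefix_albedo.png` etc., plus a lossless float container
#' (`prefix.rds`) holding the exact arrays for round-trip use.
#'
#' @param dec `endo_decomposition`.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_decomposition <- function(dec, prefix) {
  stopifnot(inherits(dec, "endo_decomposition"))
  write_frame(dec$A, paste0(prefix, "_albedo.png"))
  write_frame(pmin(dec$S, 1), paste0(prefix, "_shading.png"))
  write_frame(pmin(dec$M, 1), paste0(prefix, "_specular.png"))
  saveRDS(list(A = dec$A, S = dec$S, M = dec$M), paste0(prefix, ".rds"))
  invisible(prefix)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(prefix) {
  x <- readRDS(paste0(prefix, ".rds"))
  decomposition(x$A, x$S, x$M)
}

#' Binarize the specular residual I - AS
#'
#' The inference-time specular mask: the residual between the image and its
#' diffuse reconstruction is put on the 8-bit scale and thresholded
#' (`threshold = 50` by default, i.e. 50/255). The residual is reduced across
#' channels by its maximum (speculars are near-white, so the max is the most
#' sensitive reduction); `reduce = "mean"` is available.
#'
#' @param I `endo_frame` or pixel array.
#' @param AS diffuse reconstruction, same shape.
#' @param threshold 8-bit intensity threshold in `[0, 255]`.
#' @param reduce `"max"` (default) or `"mean"` channel reduction.
#' @return H x W binary (0/1) matrix.
#' @export
binarize_residual <- function(I, AS, threshold = 50, reduce = c("max", "mean")) {
  reduce <- match.arg(reduce)
  if (threshold < 0 || threshold > 255) stop("threshold must be in [0, 255]")
  px <- frame_pixels(I)
  AS <- as_pixels(if (inherits(AS, "endo_frame")) AS$pixels else AS)
  if (!all(dim(px) == dim(AS))) stop("shape mismatch between I and AS")
  resid <- pmax(px - AS, 0) * 255
  k <- dim(resid)[3]
  r <- resid[, , 1]
  if (k > 1) {
    for (j in 2:k) {
      r <- if (reduce == "max") pmax(r, resid[, , j]) else r + resid[, , j]
    }
    if (reduce == "mean") r <- r / k
  }
  (r > threshold) * 1
}
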