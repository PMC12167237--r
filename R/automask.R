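# Auto-masking: two per-pixel gates multiplied into the masked loss terms.
# mu1 drops pixels that a raw (unwarped) source already explains at least as
# well as the warp — static pixels such as burned-in UI text, which would
# otherwise drive depth to infinity. mu2 drops pixels that fell outside the
# source view. Masks gate losses and never receive gradients.

warp_pixels <- function(x) {
  if (inherits(x, "endo_warp")) x$warped else frame_pixels(x)
}

# per-pixel channel max of an H x W x C array
channel_max <- function(px) {
  k <- dim(px)[3]
  r <- px[, , 1]
  if (k > 1) for (j in 2:k) r <- pmax(r, px[, , j])
  r
}

#' Static-pixel auto-mask (mu1)
#'
#' A pixel is kept (mask 1) iff the best warped source explains it strictly
#' better than the best raw, unwarped source:
#' `min_s L_r(I_t, I_s->t) < min_s L_r(I_t, I_s)` with `L_r` the per-pixel
#' photometric map. For pixels that do not move between frames (static
#' overlays, or a static camera) the right-hand side is already minimal and
#' the strict inequality fails, so they are masked out.
#'
#' @param I_t target frame (or array).
#' @param warped_sources list of `endo_warp` results (or warped arrays), one
#'   per source frame.
#' @param raw_sources list of the corresponding unwarped source frames.
#' @param alpha SSIM share of the photometric map (same as in training).
#' @return binary H x W matrix.
#' @export
automask_static <- function(I_t, warped_sources, raw_sources, alpha = 0.85) {
  if (length(warped_sources) == 0L) stop("need at least one source")
  stopifnot(length(warped_sources) == length(raw_sources))
  it <- frame_pixels(I_t)
  minmap <- function(lst) {
    m <- NULL
    for (x in lst) {
      pm <- photometric_loss(it, frame_pixels(warp_pixels(x)), alpha)[, , 1]
      m <- if (is.null(m)) pm else pmin(m, pm)
    }
    m
  }
  (minmap(warped_sources) < minmap(raw_sources)) * 1
}

#' Out-of-view auto-mask (mu2)
#'
#' The literal rule `I_s->t > 0` on the per-pixel channel maximum: with
#' zero-padded warping, a zero sample means the pixel left the source view.
#' This also masks genuinely black source pixels; `method = "geometric"`
#' instead uses the warp's coordinate-validity mask, which does not.
#'
#' @param warped `endo_warp` (preferred) or warped array.
#' @param method `"literal"` (default, intensity > 0) or `"geometric"`.
#' @return binary H x W matrix.
#' @export
automask_valid <- function(warped, method = c("literal", "geometric")) {
  method <- match.arg(method)
  if (method == "geometric") {
    if (!inherits(warped, "endo_warp")) {
      stop("geometric validity needs an endo_warp result")
    }
    return(warped$valid * 1)
  }
  (channel_max(frame_pixels(warp_pixels(warped))) > 0) * 1
}

#' Combine the two auto-masks
#'
#' @param mu1 static-pixel mask (H x W, 0/1).
#' @param mu2 out-of-view mask (H x W, 0/1).
#' @return object of class `endo_mask_stack`: list with `mu1`, `mu2` and
#'   their elementwise product `mu`.
#' @export
combine_masks <- function(mu1, mu2) {
  mu1 <- as.matrix(mu1); mu2 <- as.matrix(mu2)
  if (!all(dim(mu1) == dim(mu2))) stop("mask shapes disagree")
  if (!all(mu1 %in% c(0, 1)) || !all(mu2 %in% c(0, 1))) {
    stop("masks must be binary")
  }
  structure(list(mu1 = mu1, mu2 = mu2, mu = mu1 * mu2),
            class = "endo_mask_stack")
}

#' @export
print.endo_mask_stack <- function(x, ...) {
  cat(sprintf("<endo_mask_stack %d x %d: mu1 %.1f%%, mu2 %.1f%%, mu %.1f%%>\n",
              nrow(x$mu), ncol(x$mu), 100 * mean(x$mu1), 100 * mean(x$mu2),
              100 * mean(x$mu)))
  invisible(x)
}
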