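# Core containers: video frames, camera intrinsics, depth maps, and their
# plain-text/PNG sidecar IO. Intensities are floats in [0,1] throughout; the
# 8-bit [0,255] scale appears only where a threshold is defined on it.

as_pixels <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(nrow(x), ncol(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("pixels must be an H x W x C array (C = 1 or 3)")
  }
  x
}

#' Create a video frame
#'
#' A frame holds an H x W x C (C = 1 or 3) array of intensities in `[0,1]`
#' plus its ordinal position in the sequence. Intensities outside `[0,1]` or
#' non-finite values are rejected.
#'
#' @param pixels numeric array H x W x 3 (or H x W / H x W x 1 for grayscale).
#' @param frame_id integer ordinal index within the sequence.
#' @return an object of class `endo_frame` with fields `pixels`, `height`,
#'   `width`, `channels`, `frame_id`.
#' @export
endo_frame <- function(pixels, frame_id = 0L) {
  px <- as_pixels(pixels)
  if (!all(is.finite(px))) stop("frame intensities must be finite")
  if (min(px) < 0 || max(px) > 1) stop("frame intensities must lie in [0,1]")
  structure(
    list(pixels = px, height = dim(px)[1], width = dim(px)[2],
         channels = dim(px)[3], frame_id = as.integer(frame_id)),
    class = "endo_frame"
  )
}

#' @export
print.endo_frame <- function(x, ...) {
  cat(sprintf("<endo_frame #%d: %d x %d x %d, range [%.3f, %.3f]>\n",
              x$frame_id, x$height, x$width, x$channels,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# pixels of a frame or a raw array, always H x W x C
frame_pixels <- function(x) {
  if (inherits(x, "endo_frame")) x$pixels else as_pixels(x)
}

#' Camera intrinsics
#'
#' Pinhole parameters in pixel units plus optional Brown-Conrady distortion
#' coefficients `(k1, k2, p1, p2, k3...)`.
#'
#' @param fx,fy focal lengths (pixels), positive.
#' @param cx,cy principal point (pixels, 0-based coordinate frame).
#' @param distortion numeric vector of distortion coefficients (may be empty).
#' @param width,height optional image size used to validate the principal
#'   point location.
#' @return object of class `endo_intrinsics`.
#' @export
endo_intrinsics <- function(fx, fy, cx, cy, distortion = numeric(0),
                            width = NULL, height = NULL) {
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive")
  if (!is.null(width) && (cx < 0 || cx > width - 1)) {
    stop("cx outside image bounds")
  }
  if (!is.null(height) && (cy < 0 || cy > height - 1)) {
    stop("cy outside image bounds")
  }
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 distortion = as.numeric(distortion)),
            class = "endo_intrinsics")
}

#' @export
print.endo_intrinsics <- function(x, ...) {
  cat(sprintf("<endo_intrinsics fx=%.2f fy=%.2f cx=%.2f cy=%.2f, %d distortion coef>\n",
              x$fx, x$fy, x$cx, x$cy, length(x$distortion)))
  invisible(x)
}

intrinsics_matrix <- function(K) {
  matrix(c(K$fx, 0, 0, 0, K$fy, 0, K$cx, K$cy, 1), 3, 3)
}

#' Metric depth map
#'
#' @param values H x W matrix of strictly positive, finite depths in scene
#'   units.
#' @return object of class `endo_depth`.
#' @export
depth_map <- function(values) {
  values <- as.matrix(values)
  if (!all(is.finite(values)) || any(values <= 0)) {
    stop("depth values must be finite and > 0")
  }
  structure(list(values = values), class = "endo_depth")
}

depth_values <- function(x) {
  if (inherits(x, "endo_depth")) x$values else as.matrix(x)
}

#' @export
print.endo_depth <- function(x, ...) {
  cat(sprintf("<endo_depth %d x %d, range [%.3f, %.3f]>\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

# ---- IO ----

#' Read a frame from a PNG file
#' @param path PNG file path.
#' @param frame_id ordinal index to attach.
#' @return `endo_frame`.
#' @export
read_frame <- function(path, frame_id = 0L) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3]  # drop alpha
  endo_frame(px, frame_id = frame_id)
}

#' Write a frame to a PNG file (8-bit)
#' @param frame `endo_frame` or pixel array.
#' @param path output path.
#' @export
write_frame <- function(frame, path) {
  px <- frame_pixels(frame)
  if (dim(px)[3] == 1L) px <- px[, , 1]
  png::writePNG(px, path)
  invisible(path)
}

#' Read/write camera intrinsics sidecar (JSON or YAML, by extension)
#' @param path sidecar path ending in `.json`, `.yaml` or `.yml`.
#' @return `endo_intrinsics`.
#' @export
read_intrinsics <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  endo_intrinsics(obj$fx, obj$fy, obj$cx, obj$cy,
                  distortion = unlist(obj$distortion %||% numeric(0)))
}

#' @rdname read_intrinsics
#' @param K `endo_intrinsics` to write.
#' @export
write_intrinsics <- function(K, path) {
  obj <- list(fx = K$fx, fy = K$fy, cx = K$cx, cy = K$cy,
              distortion = K$distortion)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read/write ground-truth depth (16-bit TIFF + JSON scale sidecar)
#'
#' Depth is stored as `depth / scale` in a 16-bit image; the multiplicative
#' `scale` (scene units at intensity 1.0) lives in `<path>.json`.
#' @param path image path (`.tif`/`.tiff`).
#' @return `endo_depth`.
#' @export
read_depth <- function(path) {
  vals <- tiff::readTIFF(path)
  side <- paste0(path, ".json")
  scale <- if (file.exists(side)) jsonlite::fromJSON(side)$scale else 1
  depth_map(pmax(as.matrix(vals) * scale, .Machine$double.eps))
}

#' @rdname read_depth
#' @param depth `endo_depth` or matrix to write.
#' @param scale scene units represented by intensity 1.0; defaults to
#'   `max(depth)` so the full 16-bit range is used.
#' @export
write_depth <- function(depth, path, scale = NULL) {
  vals <- depth_values(depth)
  if (is.null(scale)) scale <- max(vals)
  tiff::writeTIFF(vals / scale, path, bits.per.sample = 16L)
  jsonlite::write_json(list(scale = scale), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
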