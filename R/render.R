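# Deterministic renderer of colon-like scenes with complete ground truth.
# The scene is a tube (or a fronto-parallel plane) viewed from inside with a
# point light attached to the camera — the endoscope configuration, which
# makes shading view-dependent and moves specular highlights between frames
# like on real wet tissue. Every frame comes with ground-truth albedo,
# shading, specular component, depth, spot and overlay masks, pose and
# intrinsics, so the other modules can be tested without external data.

#' Describe a synthetic scene
#'
#' Defaults give a straight tube of radius 1 (scene units) and length 8,
#' a forward-moving camera with slight wobble, a seeded procedural mucosa
#' albedo with vascular streaks, inverse-square falloff shading from the
#' camera-attached light, and a handful of sharp Phong-style specular spots
#' anchored to the tube wall.
#'
#' @param geometry `"tube"` or `"plane"`.
#' @param radius tube radius, scene units.
#' @param fold_amp relative amplitude of the periodic radius modulation
#'   (haustral folds); 0 gives a straight cylinder.
#' @param fold_freq fold frequency along the axis, radians per scene unit.
#' @param length tube length (an end cap closes the far end).
#' @param plane_depth depth of the plane when `geometry = "plane"`.
#' @param resolution square image size in pixels.
#' @param n_frames number of frames along the trajectory.
#' @param step forward translation per frame, scene units.
#' @param wobble amplitude of the lateral camera sway, scene units.
#' @param motion_freq angular frequency (radians per frame) of the sway and
#'   rocking patterns; lower values give smoother, more predictable motion.
#' @param rock amplitude of the rotational camera rocking in radians;
#'   defaults to `0.4 * wobble`. Lateral sway creates depth-dependent
#'   parallax; rocking creates depth-free flow — the two are separate
#'   handles because their ratio decides how informative the sequence is
#'   about depth.
#' @param light_intensity point-light intensity `I0` (shading is
#'   `clip(I0 cos(theta)/dist^falloff, 0, 1)`).
#' @param light_falloff distance-falloff exponent; 2 is a point source,
#'   lower values approximate the extended ring illumination of an
#'   endoscope tip.
#' @param texture_contrast multiplier on the albedo texture amplitudes.
#' @param specular_strength peak specular intensity before clipping (0
#'   disables speculars).
#' @param n_spots expected number of specular spots.
#' @param spot_radius spot radius on the surface, scene units.
#' @param phong_exponent Phong lobe exponent (sharpness of highlights).
#' @param overlay add a static burned-in text-like overlay.
#' @param overlay_intensity gray level of the overlay.
#' @param fov_scale focal length as a fraction of the resolution.
#' @param seed RNG seed; the whole sequence is a pure function of the spec.
#' @return object of class `endo_scene_spec`.
#' @export
scene_spec <- function(geometry = c("tube", "plane"), radius = 1,
                       fold_amp = 0.2, fold_freq = 2.2, length = 8,
                       plane_depth = 2, resolution = 128L, n_frames = 16L,
                       step = 0.06, wobble = 0.01, rock = NULL,
                       motion_freq = 0.7,
                       light_intensity = 0.9, light_falloff = 2,
                       texture_contrast = 1, specular_strength = 1.35,
                       n_spots = 6L, spot_radius = 0.28, phong_exponent = 4000,
                       overlay = FALSE, overlay_intensity = 0.55,
                       fov_scale = 0.8, seed = 7L) {
  geometry <- match.arg(geometry)
  stopifnot(radius > 0, resolution > 1, n_frames >= 1)
  if (is.null(rock)) rock <- 0.4 * wobble
  # keep the whole trajectory inside the tube (camera starts at z = 0.5)
  length <- max(length, 0.5 + step * (n_frames - 1) + 2 * radius)
  structure(as.list(environment()), class = "endo_scene_spec")
}

# camera-to-world poses along the trajectory
scene_trajectory <- function(spec) {
  s <- spec$motion_freq / 0.7
  lapply(seq_len(spec$n_frames), function(i) {
    k <- i - 1L
    tr <- c(spec$wobble * sin(0.7 * s * k), spec$wobble * cos(0.9 * s * k),
            0.5 + spec$step * k)
    ra <- spec$rock
    rot <- pose_vector_to_transform(
      c(ra * sin(0.6 * s * k), ra * cos(0.8 * s * k),
        0.5 * ra * sin(0.5 * s * k), 0, 0, 0))$R
    rigid_transform(rot, tr)
  })
}

scene_intrinsics <- function(spec) {
  res <- spec$resolution
  endo_intrinsics(fx = spec$fov_scale * res, fy = spec$fov_scale * res,
                  cx = (res - 1) / 2 + 0.02 * res,
                  cy = (res - 1) / 2 - 0.015 * res)
}

# static text-like overlay mask (three bars + a block, top-left corner)
overlay_mask <- function(H, W) {
  m <- matrix(0, H, W)
  bar <- max(3L, round(H / 14))
  r0 <- max(2L, round(0.06 * H))
  c0 <- max(2L, round(0.06 * W))
  m[r0:(r0 + bar), c0:(c0 + round(0.3 * W))] <- 1
  m[(r0 + 2L * bar):(r0 + 3L * bar), c0:(c0 + round(0.22 * W))] <- 1
  m[round(0.78 * H):round(0.92 * H), round(0.78 * W):round(0.92 * W)] <- 1
  m
}

# procedural mucosa albedo at surface coordinates (phi wraps, z along axis)
scene_albedo <- function(phi, z, pars, contrast = 1) {
  base <- c(0.74, 0.5, 0.46)
  v <- 0
  for (j in seq_len(nrow(pars$waves))) {
    w <- pars$waves[j, ]
    v <- v + w[3] * sin(w[1] * phi + w[2] * z + w[4])
  }
  streak <- exp(-((sin(pars$streak[1] * phi + pars$streak[2] * z +
                         pars$streak[3]))^2) / 0.02)
  A <- array(0, c(length(phi), 3))
  dim(v) <- NULL; dim(streak) <- NULL
  A[, 1] <- base[1] + contrast * (0.16 * v - 0.10 * streak)
  A[, 2] <- base[2] + contrast * (0.13 * v - 0.16 * streak)
  A[, 3] <- base[3] + contrast * (0.10 * v - 0.14 * streak)
  pmin(pmax(A, 0.05), 0.95)
}

scene_texture_pars <- function(spec) {
  rs <- spec$seed
  set.seed(rs)
  waves <- cbind(c(sample(2:6, 4, replace = TRUE), sample(8:14, 1)),  # angular freq
                 c(stats::runif(4, 0.8, 2.5), stats::runif(1, 2.5, 5)),  # axial freq
                 c(stats::runif(4, 0.35, 0.6), 0.35),       # amplitude share
                 stats::runif(5, 0, 2 * pi))                # phase
  streak <- c(3, stats::runif(1, 0.5, 1.2), stats::runif(1, 0, pi))
  spots <- NULL
  if (spec$n_spots > 0) {
    spots <- cbind(phi = stats::runif(spec$n_spots, -pi, pi),
                   z = stats::runif(spec$n_spots, 1.2, spec$length - 1.5),
                   rad = spec$spot_radius * stats::runif(spec$n_spots, 0.8, 1.3))
  }
  list(waves = waves, streak = streak, spots = spots)
}

#' Render a synthetic sequence with ground truth
#'
#' @param spec `endo_scene_spec`.
#' @return list of `endo_rendered` frames, each with fields `frame`
#'   (`endo_frame`), `gt` (list `A`, `S`, `M`, `spot_mask`, `D`
#'   (`endo_depth`), `overlay`), `pose` (camera-to-world `endo_transform`)
#'   and `K`. The sequence spec is attached as attribute `"spec"`.
#' @export
render_sequence <- function(spec) {
  stopifnot(inherits(spec, "endo_scene_spec"))
  K <- scene_intrinsics(spec)
  poses <- scene_trajectory(spec)
  pars <- scene_texture_pars(spec)
  res <- spec$resolution
  ov <- if (spec$overlay) overlay_mask(res, res) else matrix(0, res, res)
  ref_cam <- poses[[max(1L, ceiling(spec$n_frames / 2))]]$t  # spot tilt target
  out <- vector("list", spec$n_frames)
  for (i in seq_len(spec$n_frames)) {
    out[[i]] <- render_one(spec, K, poses[[i]], pars, ov, ref_cam, i - 1L)
  }
  attr(out, "spec") <- spec
  attr(out, "K") <- K
  out
}

render_one <- function(spec, K, pose, pars, ov, ref_cam, frame_id) {
  res <- spec$resolution
  dirs <- camera_dirs(res, res, K)
  dcx <- c(dirs$x); dcy <- c(dirs$y); dcz <- rep(1, length(dcx))
  R <- pose$R; o <- pose$t
  dwx <- R[1, 1] * dcx + R[1, 2] * dcy + R[1, 3] * dcz
  dwy <- R[2, 1] * dcx + R[2, 2] * dcy + R[2, 3] * dcz
  dwz <- R[3, 1] * dcx + R[3, 2] * dcy + R[3, 3] * dcz

  if (spec$geometry == "plane") {
    # plane fixed in the world at z = 0.5 + plane_depth (0.5 = trajectory start)
    s <- (0.5 + spec$plane_depth - o[3]) / dwz
    nx <- rep(0, length(s)); ny <- rep(0, length(s)); nz <- rep(-1, length(s))
    is_cap <- rep(TRUE, length(s))
  } else {
    s_cap <- ifelse(dwz > 1e-9, (spec$length - o[3]) / dwz, Inf)
    if (spec$fold_amp == 0) {
      a <- dwx^2 + dwy^2
      b <- 2 * (o[1] * dwx + o[2] * dwy)
      cc <- o[1]^2 + o[2]^2 - spec$radius^2
      disc <- pmax(b^2 - 4 * a * cc, 0)
      s_wall <- ifelse(a > 1e-12, (-b + sqrt(disc)) / (2 * a), Inf)
    } else {
      # generalized cylinder with haustral folds: march to the first exit
      # of x^2 + y^2 < r(z)^2, then bisect
      fofs <- function(s) {
        px <- o[1] + s * dwx; py <- o[2] + s * dwy; pz <- o[3] + s * dwz
        rz <- spec$radius * (1 + spec$fold_amp * sin(spec$fold_freq * pz))
        px * px + py * py - rz * rz
      }
      ds <- 0.05
      smax <- pmin(s_cap, (spec$length + 2 * spec$radius) / pmax(dwz, 0.05))
      s_lo <- rep(0, length(dwx))
      s_hi <- rep(NA_real_, length(dwx))
      s_try <- rep(ds, length(dwx))
      for (it in seq_len(ceiling(max(smax) / ds) + 2L)) {
        open <- is.na(s_hi) & s_try <= smax + ds
        if (!any(open)) break
        fv <- fofs(s_try)
        crossed <- open & fv >= 0
        s_hi[crossed] <- s_try[crossed]
        s_lo[open & !crossed] <- s_try[open & !crossed]
        s_try <- s_try + ds
      }
      s_hi[is.na(s_hi)] <- Inf
      bad <- is.finite(s_hi)
      for (it in 1:40) {
        mid <- ifelse(bad, (s_lo + s_hi) / 2, 1)
        fm <- fofs(mid)
        below <- fm < 0
        s_lo <- ifelse(bad & below, mid, s_lo)
        s_hi <- ifelse(bad & !below, mid, s_hi)
      }
      s_wall <- ifelse(is.finite(s_hi), (s_lo + s_hi) / 2, Inf)
    }
    is_cap <- s_cap < s_wall
    s <- pmin(s_wall, s_cap)
    if (any(!is.finite(s))) stop("ray missed the scene geometry")
    Px <- o[1] + s * dwx; Py <- o[2] + s * dwy; Pz0 <- o[3] + s * dwz
    rz <- spec$radius * (1 + spec$fold_amp * sin(spec$fold_freq * Pz0))
    drdz <- spec$radius * spec$fold_amp * spec$fold_freq * cos(spec$fold_freq * Pz0)
    nn <- sqrt(Px^2 + Py^2 + (rz * drdz)^2)
    nx <- ifelse(is_cap, 0, -Px / nn)
    ny <- ifelse(is_cap, 0, -Py / nn)
    nz <- ifelse(is_cap, -1, rz * drdz / nn)
  }
  Px <- o[1] + s * dwx; Py <- o[2] + s * dwy; Pz <- o[3] + s * dwz
  # light co-located with the camera
  Lx <- o[1] - Px; Ly <- o[2] - Py; Lz <- o[3] - Pz
  dist <- sqrt(Lx^2 + Ly^2 + Lz^2)
  lx <- Lx / dist; ly <- Ly / dist; lz <- Lz / dist
  costh <- pmax(nx * lx + ny * ly + nz * lz, 0)
  S <- pmin(spec$light_intensity * costh / dist^spec$light_falloff, 1)

  phi <- atan2(Py, Px)
  zs <- ifelse(is_cap, spec$length + 0.5 * sqrt(Px^2 + Py^2), Pz)
  A <- scene_albedo(phi, zs, pars, contrast = spec$texture_contrast)

  M <- rep(0, length(s))
  if (!is.null(pars$spots) && spec$specular_strength > 0) {
    for (j in seq_len(nrow(pars$spots))) {
      sp <- pars$spots[j, ]
      dphi <- atan2(sin(phi - sp[1]), cos(phi - sp[1]))
      dsurf <- sqrt((spec$radius * dphi)^2 + (Pz - sp[2])^2)
      # plateau with a sharp logistic rim (wet-tissue bump facet)
      w <- 1 / (1 + exp((dsurf - sp[3]) / (0.03 * sp[3])))
      w[is_cap] <- 0
      # bump normal tilted toward the reference camera position
      tx <- ref_cam[1] - Px; ty <- ref_cam[2] - Py; tz <- ref_cam[3] - Pz
      tn <- sqrt(tx^2 + ty^2 + tz^2)
      bx <- (1 - w) * nx + w * tx / tn
      by <- (1 - w) * ny + w * ty / tn
      bz <- (1 - w) * nz + w * tz / tn
      bn <- sqrt(bx^2 + by^2 + bz^2)
      ndv <- pmax((bx * lx + by * ly + bz * lz) / bn, 0)
      M <- M + w * spec$specular_strength * ndv^spec$phong_exponent
    }
  }
  H <- res; W <- res
  Sm <- array(S, c(H, W, 1))
  Aa <- array(A, c(H, W, 3))
  Mc <- pmin(M, 1.5)
  Ma <- array(rep(Mc, 3), c(H, W, 3))
  I <- pmin(pmax(Aa * array(Sm, c(H, W, 3)) + Ma, 0), 1)
  if (any(ov > 0)) {
    for (ch in 1:3) {
      Ic <- I[, , ch]
      Ic[ov > 0] <- spec$overlay_intensity
      I[, , ch] <- Ic
    }
  }
  spot <- matrix((Mc >= 0.92) * 1, H, W)
  structure(list(
    frame = endo_frame(I, frame_id = frame_id),
    gt = list(A = Aa, S = Sm, M = Ma, spot_mask = spot,
              D = depth_map(matrix(s, H, W)), overlay = ov),
    pose = pose, K = K
  ), class = "endo_rendered")
}

#' @export
print.endo_rendered <- function(x, ...) {
  cat(sprintf("<endo_rendered #%d: %d x %d, depth [%.2f, %.2f], %.2f%% specular>\n",
              x$frame$frame_id, x$frame$height, x$frame$width,
              min(x$gt$D$values), max(x$gt$D$values), 100 * mean(x$gt$spot_mask)))
  invisible(x)
}

#' Relative pose between two rendered frames
#'
#' Converts the stored camera-to-world poses into the target-to-source
#' camera transform consumed by [inverse_warp()].
#'
#' @param target,source `endo_rendered` frames.
#' @return `endo_transform` `T_t_to_s`.
#' @export
relative_pose <- function(target, source) {
  compose_transform(invert_transform(source$pose), target$pose)
}

# ---- preprocessing utilities ----

# bilinear resize of an H x W x C array (exact identity at equal size)
bilinear_resize <- function(px, h2, w2) {
  px <- as_pixels(px)
  H <- dim(px)[1]; W <- dim(px)[2]
  u <- matrix(rep((seq_len(w2) - 0.5) * W / w2 - 0.5, each = h2), h2, w2)
  v <- matrix(rep((seq_len(h2) - 0.5) * H / h2 - 0.5, times = w2), h2, w2)
  u <- pmin(pmax(u, 0), W - 1)
  v <- pmin(pmax(v, 0), H - 1)
  vof(nd_grid_sample(px, u, v)$out)
}

#' Centre-crop to square and resize
#'
#' The standard preprocessing for endoscopy video: crop the central square,
#' then resize to `size` x `size` (default 288) with bilinear sampling.
#'
#' @param I frame or H x W x C array.
#' @param size output side length in pixels.
#' @return `endo_frame` of `size` x `size`.
#' @export
crop_resize <- function(I, size = 288L) {
  stopifnot(size > 0)
  px <- frame_pixels(I)
  H <- dim(px)[1]; W <- dim(px)[2]
  side <- min(H, W)
  r0 <- (H - side) %/% 2L
  c0 <- (W - side) %/% 2L
  px <- px[r0 + seq_len(side), c0 + seq_len(side), , drop = FALSE]
  if (side != size) px <- bilinear_resize(px, size, size)
  endo_frame(pmin(pmax(px, 0), 1),
             frame_id = if (inherits(I, "endo_frame")) I$frame_id else 0L)
}

#' Undistort an image (Brown-Conrady model)
#'
#' For every output pixel the ideal (undistorted) normalized coordinates are
#' pushed through the forward distortion model to find the source location
#' in the distorted input, which is then sampled bilinearly. All-zero
#' coefficients reproduce the input exactly.
#'
#' @param I frame or array.
#' @param K `endo_intrinsics` carrying `(k1, k2, p1, p2[, k3])` in
#'   `K$distortion`.
#' @return `endo_frame`.
#' @export
undistort <- function(I, K) {
  px <- frame_pixels(I)
  H <- dim(px)[1]; W <- dim(px)[2]
  d <- K$distortion
  if (length(d) == 0 || all(d == 0)) {
    return(endo_frame(px, frame_id = if (inherits(I, "endo_frame")) I$frame_id else 0L))
  }
  k1 <- d[1]; k2 <- if (length(d) >= 2) d[2] else 0
  p1 <- if (length(d) >= 3) d[3] else 0
  p2 <- if (length(d) >= 4) d[4] else 0
  k3 <- if (length(d) >= 5) d[5] else 0
  dirs <- camera_dirs(H, W, K)
  x <- dirs$x; y <- dirs$y
  r2 <- x^2 + y^2
  rad <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
  xd <- x * rad + 2 * p1 * x * y + p2 * (r2 + 2 * x^2)
  yd <- y * rad + p1 * (r2 + 2 * y^2) + 2 * p2 * x * y
  u <- K$fx * xd + K$cx
  v <- K$fy * yd + K$cy
  warped <- vof(nd_grid_sample(px, u, v)$out)
  endo_frame(pmin(pmax(warped, 0), 1),
             frame_id = if (inherits(I, "endo_frame")) I$frame_id else 0L)
}

# ---- sequence IO (the on-disk layout consumed by fit/evaluate) ----

#' Write a rendered sequence to a directory
#'
#' Layout: `frame_%04d.png`, `depth_%04d.tif` (+ JSON scale sidecars),
#' `poses.json` (camera-to-world rotations/translations),
#' `intrinsics.json`, and optional ground-truth decomposition
#' (`albedo/shading/specular_%04d.png` plus a lossless `.rds` float
#' container per frame).
#'
#' @param seq list of `endo_rendered` (from [render_sequence()]).
#' @param dir output directory (created).
#' @param write_gt also write ground-truth depth and decomposition.
#' @return `dir`, invisibly.
#' @export
write_sequence <- function(seq, dir, write_gt = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  poses <- list()
  for (i in seq_along(seq)) {
    fr <- seq[[i]]
    id <- sprintf("%04d", i - 1L)
    write_frame(fr$frame, file.path(dir, paste0("frame_", id, ".png")))
    if (write_gt) {
      write_depth(fr$gt$D, file.path(dir, paste0("depth_", id, ".tif")))
      saveRDS(fr$gt, file.path(dir, paste0("gt_", id, ".rds")))
    }
    poses[[i]] <- list(R = fr$pose$R, t = fr$pose$t)
  }
  jsonlite::write_json(poses, file.path(dir, "poses.json"), digits = NA)
  write_intrinsics(seq[[1]]$K, file.path(dir, "intrinsics.json"))
  invisible(dir)
}

#' Read a frame sequence directory
#'
#' @param dir directory produced by [write_sequence()] (ground truth is
#'   loaded when present).
#' @return list with `frames` (list of `endo_frame`), `K`, and optional
#'   `depths` / `poses`.
#' @export
read_sequence <- function(dir) {
  fpaths <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$", full.names = TRUE))
  if (length(fpaths) == 0) stop("no frame_*.png found in ", dir)
  frames <- lapply(seq_along(fpaths), function(i) read_frame(fpaths[i], frame_id = i - 1L))
  K <- NULL
  kp <- file.path(dir, "intrinsics.json")
  if (file.exists(kp)) K <- read_intrinsics(kp)
  dpaths <- sort(list.files(dir, pattern = "^depth_\\d+\\.tif$", full.names = TRUE))
  depths <- if (length(dpaths)) lapply(dpaths, read_depth) else NULL
  poses <- NULL
  pp <- file.path(dir, "poses.json")
  if (file.exists(pp)) {
    raw <- jsonlite::fromJSON(pp, simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
    poses <- lapply(raw, function(p) rigid_transform(matrix(unlist(p$R), 3, 3),
                                                     unlist(p$t)))
  }
  list(frames = frames, K = K, depths = depths, poses = poses)
}
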