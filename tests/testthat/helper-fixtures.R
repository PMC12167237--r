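# Shared fixtures, rendered once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

# small tube scene with speculars (the default study conditions, 96 px)
fixture_tube <- function() {
  if (is.null(.fixtures$tube)) {
    .fixtures$tube <- render_sequence(scene_spec(resolution = 96L, n_frames = 8L))
  }
  .fixtures$tube
}

# 64 px tube with the static overlay burned in (training smoke tests)
fixture_overlay <- function() {
  if (is.null(.fixtures$ov)) {
    .fixtures$ov <- render_sequence(
      scene_spec(resolution = 64L, n_frames = 6L, step = 0.22, overlay = TRUE))
  }
  .fixtures$ov
}

# textured plane with overlay and lateral/rotational camera motion: the
# clean setting for the static-pixel auto-mask semantics (no view-dependent
# shading confound from the co-located light moving down a tube)
fixture_plane_overlay <- function() {
  if (is.null(.fixtures$pov)) {
    .fixtures$pov <- render_sequence(
      scene_spec(geometry = "plane", plane_depth = 2, resolution = 128L,
                 n_frames = 6L, step = 0.02, wobble = 0.12,
                 light_falloff = 0.7, texture_contrast = 2.2, overlay = TRUE))
  }
  .fixtures$pov
}

# binary mask dilation by r pixels (4-neighbourhood, iterated)
dilate_mask <- function(m, r) {
  m <- m > 0
  H <- nrow(m); W <- ncol(m)
  for (i in seq_len(r)) {
    m <- m | rbind(m[-1, ], FALSE) | rbind(FALSE, m[-H, ]) |
      cbind(m[, -1], FALSE) | cbind(FALSE, m[, -W])
  }
  m
}

# random smooth-ish RGB image
random_image <- function(H, W, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(H * W * 3), dim = c(H, W, 3))
}
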