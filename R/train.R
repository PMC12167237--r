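# The training loop: every step decomposes target and source frames,
# predicts target depth and relative poses, warps the source diffuse
# reconstructions (and albedos) into the target view, gates the masked
# losses with the auto-masks, and takes one Adam update on the total
# objective. Masks and the cached specular-free images are constants with
# respect to the gradient.

#' Training configuration
#'
#' @param use_inpainting use the segmentation+inpainting preprocessor to
#'   build the specular-free supervision image `I_rem` (the "IM" ablation
#'   flag); when off, `I_rem := I`.
#' @param use_automask apply the static-pixel auto-mask `mu1` (the "AM"
#'   flag); when off `mu1` is all ones and `mu == mu2`.
#' @param use_adjustment accepted for configuration completeness only; the
#'   shading adjustment network is intentionally absent and `TRUE` raises an
#'   error.
#' @param weights `endo_loss_weights`.
#' @param d_min,d_max depth range bounds, scene units.
#' @param epochs,lr Adam epochs and learning rate.
#' @param lr_decay_frac,lr_decay_factor after `lr_decay_frac` of the
#'   planned steps the learning rate is multiplied by `lr_decay_factor`
#'   (1 disables the decay).
#' @param pose_lr_mult learning-rate multiplier for the pose network
#'   (relative to `lr`). The pose regressor is the smallest network and is
#'   often the optimization bottleneck when training from scratch.
#' @param seed single seed fanning out to weight init and data shuffling.
#' @param source_offsets temporal source-frame offsets relative to the
#'   target (default `c(-1, 1)`).
#' @param preset network size preset, see [endo_networks()].
#' @param min_reprojection aggregate the reprojection map over sources by
#'   per-pixel minimum (default) instead of mean.
#' @param n_scales number of image-pyramid scales for the photometric
#'   terms (1 = full resolution only). Multi-scale supervision lets the
#'   pose/depth gradients capture displacements larger than a pixel, which
#'   training from scratch requires; 4 by default.
#' @param bootstrap_steps number of initial steps during which the
#'   reprojection term warps the raw source frames instead of their diffuse
#'   reconstructions. Early in from-scratch training the decomposition
#'   output is still near-uniform and carries no texture for the warp to
#'   match, so depth and pose would receive no signal; the bootstrap phase
#'   feeds them the raw photometric signal first and then hands over to the
#'   non-Lambertian objective. 0 disables.
#' @param valid_mask `"literal"` (`I_s->t > 0`) or `"geometric"` for `mu2`.
#' @param cache_dir preprocessing cache directory (default: per-session
#'   tempdir).
#' @param log_csv optional CSV path for the per-step loss log.
#' @param batch_size triplets per optimizer step (gradients are
#'   accumulated and averaged across the batch).
#' @param max_steps cap on total optimizer steps (useful for short runs).
#' @return object of class `endo_train_config`.
#' @export
train_config <- function(use_inpainting = TRUE, use_automask = TRUE,
                         use_adjustment = FALSE, weights = loss_weights(),
                         d_min = 0.1, d_max = 10, epochs = 20, lr = 1e-4,
                         lr_decay_frac = 0.6, lr_decay_factor = 1 / 3,
                         pose_lr_mult = 1,
                         seed = 42L, source_offsets = c(-1L, 1L),
                         preset = "tiny", min_reprojection = TRUE,
                         n_scales = 4L, bootstrap_steps = 300L,
                         valid_mask = c("literal", "geometric"),
                         batch_size = 1L,
                         cache_dir = NULL, log_csv = NULL, max_steps = Inf) {
  valid_mask <- match.arg(valid_mask)
  if (isTRUE(use_adjustment)) {
    stop("the shading adjustment network is not part of this model; ",
         "the specular component replaces it")
  }
  stopifnot(d_min > 0, d_min < d_max, epochs >= 1, lr > 0,
            length(source_offsets) >= 1, n_scales >= 1)
  structure(list(use_inpainting = use_inpainting, use_automask = use_automask,
                 use_adjustment = FALSE, weights = weights, d_min = d_min,
                 d_max = d_max, epochs = epochs, lr = lr,
                 lr_decay_frac = lr_decay_frac,
                 lr_decay_factor = lr_decay_factor,
                 pose_lr_mult = pose_lr_mult,
                 seed = as.integer(seed),
                 source_offsets = as.integer(source_offsets), preset = preset,
                 min_reprojection = min_reprojection,
                 n_scales = as.integer(n_scales),
                 bootstrap_steps = as.integer(bootstrap_steps),
                 valid_mask = valid_mask,
                 batch_size = as.integer(batch_size),
                 cache_dir = cache_dir, log_csv = log_csv,
                 max_steps = max_steps),
            class = "endo_train_config")
}

# ---- Adam ----

adam_new <- function(params, lr, lrs = NULL, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, warmup = 100L) {
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$lr <- lr
  e$lrs <- if (is.null(lrs)) rep(lr, length(params)) else lrs
  e$warmup <- warmup
  e$scale <- 1
  e$b1 <- beta1; e$b2 <- beta2; e$eps <- eps
  e$t <- 0L
  e$m <- lapply(params, function(p) p$v * 0)
  e$u <- lapply(params, function(p) p$v * 0)
  e
}

adam_step <- function(opt, clip_norm = 10) {
  if (is.finite(clip_norm)) {
    gn2 <- 0
    for (p in opt$params) if (!is.null(p$g)) gn2 <- gn2 + sum(p$g^2)
    gn <- sqrt(gn2)
    if (gn > clip_norm) {
      sc <- clip_norm / gn
      for (p in opt$params) if (!is.null(p$g)) p$g <- p$g * sc
    }
  }
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$b1^opt$t
  c2 <- 1 - opt$b2^opt$t
  ramp <- if (opt$warmup > 0) min(1, opt$t / opt$warmup) else 1
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$g
    if (is.null(g)) next
    opt$m[[i]] <- opt$b1 * opt$m[[i]] + (1 - opt$b1) * g
    opt$u[[i]] <- opt$b2 * opt$u[[i]] + (1 - opt$b2) * g * g
    p$v <- p$v - opt$lrs[i] * opt$scale * ramp *
      (opt$m[[i]] / c1) / (sqrt(opt$u[[i]] / c2) + opt$eps)
    p$g <- NULL
  }
  invisible(opt)
}

# optimizer over the full bundle with the pose-net lr multiplier applied
make_optimizer <- function(nets, cfg) {
  pd <- net_params(list(nets$depth, nets$decompose))
  pp <- net_params(nets$pose)
  adam_new(c(pd, pp), cfg$lr,
           lrs = c(rep(cfg$lr, length(pd)),
                   rep(cfg$lr * cfg$pose_lr_mult, length(pp))))
}

# ---- one optimization step ----

# intrinsics for a 2^k-downsampled image (pixel-center convention)
scaled_intrinsics <- function(K, f) {
  endo_intrinsics(K$fx / f, K$fy / f,
                  (K$cx + 0.5) / f - 0.5, (K$cy + 0.5) / f - 0.5,
                  distortion = K$distortion)
}

# repeated 2x average pooling (works on nodes and plain arrays)
pool_times <- function(x, k) {
  while (k > 0) {
    x <- nd_avgpool2(x)
    k <- k - 1
  }
  x
}

# builds the full training graph for one target + its sources; returns the
# scalar loss node plus numeric diagnostics. Photometric terms are computed
# on an image pyramid (cfg$n_scales levels): coarse levels let the
# pose/depth gradients see displacements beyond one pixel.
training_graph <- function(target, sources, target_rem, sources_rem, K,
                           nets, cfg, bootstrap = FALSE) {
  wts <- cfg$weights
  alpha <- wts$alpha
  H <- dim(target)[1]; W <- dim(target)[2]
  S <- cfg$n_scales
  dec_t <- decompose_forward(nets, target)
  AS_t <- nd_clamp(nd_mul(dec_t$A, nd_repc(dec_t$S, 3L)), 0, 1)
  D_t <- depth_forward(nets, target, cfg$d_min, cfg$d_max)

  # per-scale constants
  tgt_k <- list(target); rem_k <- list(target_rem)
  if (S > 1) {
    for (k in 2:S) {
      tgt_k[[k]] <- nd_avgpool2(tgt_k[[k - 1]])
      rem_k[[k]] <- nd_avgpool2(rem_k[[k - 1]])
    }
  }
  # per-scale nodes shared across sources
  ASt_k <- list(AS_t); At_k <- list(dec_t$A); D_k <- list(D_t)
  if (S > 1) {
    for (k in 2:S) {
      ASt_k[[k]] <- nd_avgpool2(ASt_k[[k - 1]])
      At_k[[k]] <- nd_avgpool2(At_k[[k - 1]])
      D_k[[k]] <- nd_avgpool2(D_k[[k - 1]])
    }
  }
  L_d_t <- nd_mean(nd_photometric(AS_t, target_rem, alpha))

  Lr_scale <- vector("list", S)   # per-scale min-over-source maps
  La_scale <- vector("list", S)
  pmw_scale <- vector("list", S)  # numeric mu1 ingredients per scale
  pmr_scale <- vector("list", S)
  mu2_scale <- rep(list(NULL), S)
  Ld_s_sum <- NULL
  for (si in seq_along(sources)) {
    I_s <- sources[[si]]
    dec_s <- decompose_forward(nets, I_s)
    AS_s <- nd_clamp(nd_mul(dec_s$A, nd_repc(dec_s$S, 3L)), 0, 1)
    Ld_s <- nd_mean(nd_photometric(AS_s, sources_rem[[si]], alpha))
    Ld_s_sum <- if (is.null(Ld_s_sum)) Ld_s else nd_add(Ld_s_sum, Ld_s)
    v6 <- pose_forward(nets, target, I_s)
    Rt <- nd_pose_to_Rt(v6)
    # during the bootstrap phase the reprojection term warps the raw source
    # (the decomposition has no texture yet to carry the signal)
    lr_src <- if (bootstrap) I_s else AS_s
    stack_s <- nd_concat_c(list(lr_src, dec_s$A, I_s))
    for (k in seq_len(S)) {
      f <- 2^(k - 1)
      Kk <- if (k == 1) K else scaled_intrinsics(K, f)
      stk <- pool_times(stack_s, k - 1)
      wr <- nd_inverse_warp(stk, D_k[[k]], Kk, Rt)
      ASw <- nd_slice_c(wr$out, 1:3)
      Aw <- nd_slice_c(wr$out, 4:6)
      Iw <- nd_detach(nd_slice_c(wr$out, 7:9))
      lr_s <- nd_photometric(ASw, rem_k[[k]], alpha)
      Lr_scale[[k]] <- if (is.null(Lr_scale[[k]])) lr_s else {
        if (cfg$min_reprojection) nd_min2(Lr_scale[[k]], lr_s)
        else nd_add(Lr_scale[[k]], lr_s)
      }
      la_s <- nd_cmean(nd_abs(nd_sub(At_k[[k]], Aw)))
      La_scale[[k]] <- if (is.null(La_scale[[k]])) la_s
                       else nd_add(La_scale[[k]], la_s)
      mu2_s <- if (cfg$valid_mask == "literal") {
        (channel_max(Iw) > 0) * 1
      } else {
        wr$valid * 1
      }
      mu2_scale[[k]] <- if (is.null(mu2_scale[[k]])) mu2_s
                        else pmax(mu2_scale[[k]], mu2_s)
      if (k == 1L) {
        # static-pixel evidence is gathered at full resolution only; the
        # coarse-scale masks are majority-pooled from it
        pmw <- photometric_loss(target, Iw, alpha)[, , 1]
        pmr <- photometric_loss(target, I_s, alpha)[, , 1]
        pmw_scale[[1]] <- if (is.null(pmw_scale[[1]])) pmw
                          else pmin(pmw_scale[[1]], pmw)
        pmr_scale[[1]] <- if (is.null(pmr_scale[[1]])) pmr
                          else pmin(pmr_scale[[1]], pmr)
      }
    }
  }
  ns <- length(sources)
  Ld_s_mean <- if (ns > 1) nd_affine(Ld_s_sum, 1 / ns) else Ld_s_sum
  mu1_full <- if (cfg$use_automask) {
    (pmw_scale[[1]] < pmr_scale[[1]]) * 1
  } else {
    matrix(1, H, W)
  }
  L_r <- NULL; L_a <- NULL
  masks <- NULL
  mu1_k <- mu1_full
  for (k in seq_len(S)) {
    lr_k <- Lr_scale[[k]]
    if (!cfg$min_reprojection && ns > 1) lr_k <- nd_affine(lr_k, 1 / ns)
    la_k <- if (ns > 1) nd_affine(La_scale[[k]], 1 / ns) else La_scale[[k]]
    if (k > 1) {
      mu1_k <- (nd_avgpool2(array(mu1_k, c(dim(mu1_k), 1)))[, , 1] > 0.5) * 1
    }
    mk <- combine_masks(mu1_k, mu2_scale[[k]])
    if (k == 1) masks <- mk  # full-resolution masks reported
    mu_arr <- array(mk$mu, c(dim(mk$mu), 1))
    lr_red <- nd_masked_mean(lr_k, mu_arr)
    la_red <- nd_masked_mean(la_k, mu_arr)
    L_r <- if (is.null(L_r)) lr_red else nd_add(L_r, lr_red)
    L_a <- if (is.null(L_a)) la_red else nd_add(L_a, la_red)
  }
  if (S > 1) {
    L_r <- nd_affine(L_r, 1 / S)
    L_a <- nd_affine(L_a, 1 / S)
  }
  L_es <- nd_smoothness(D_t, target)
  total <- nd_add(
    nd_add(nd_affine(nd_add(L_d_t, Ld_s_mean), wts$lambda_d),
           nd_affine(L_a, wts$lambda_a)),
    nd_add(nd_affine(L_r, wts$lambda_r), nd_affine(L_es, wts$lambda_es))
  )
  list(total = total,
       per_term = list(L_d_t = as.numeric(vof(L_d_t)),
                       L_d_s = as.numeric(vof(Ld_s_mean)),
                       L_a = as.numeric(vof(L_a)),
                       L_r = as.numeric(vof(L_r)),
                       L_es = as.numeric(vof(L_es))),
       per_pixel_r = nd_detach(Lr_scale[[1]]), masks = masks)
}

#' One training step on a target/source batch
#'
#' Runs the full forward pass, backpropagates, and applies one Adam update.
#' The batch is a list with `target` (frame or array), `sources` (list),
#' `target_rem` / `sources_rem` (specular-free counterparts; defaulting to
#' the raw images), and `K`.
#'
#' @param batch batch list as above.
#' @param nets `endo_networks`.
#' @param cfg `endo_train_config`.
#' @param opt optimizer state from a previous call, or `NULL` to create one.
#' @param bootstrap use the raw-frame reprojection source (see
#'   `bootstrap_steps` in [train_config()]).
#' @return `endo_loss_report` with the optimizer attached as attribute
#'   `"opt"` and the mask stack as `"masks"`.
#' @export
# forward + backward on one triplet; leaves gradients accumulated on the
# parameters (no optimizer update)
train_forward_backward <- function(batch, nets, cfg, bootstrap = FALSE) {
  target <- frame_pixels(batch$target)
  sources <- lapply(batch$sources, frame_pixels)
  target_rem <- frame_pixels(batch$target_rem %||% batch$target)
  sources_rem <- if (is.null(batch$sources_rem)) sources else
    lapply(batch$sources_rem, frame_pixels)
  gr <- with_tape({
    g <- training_graph(target, sources, target_rem, sources_rem, batch$K,
                        nets, cfg, bootstrap = bootstrap)
    if (!is.finite(vof(g$total))) {
      bad <- names(g$per_term)[!vapply(g$per_term, is.finite, logical(1))]
      stop("non-finite training loss (term: ",
           paste(if (length(bad)) bad else "total", collapse = ", "), ")")
    }
    ad_backward(g$total)
    g
  })
  structure(list(total = as.numeric(vof(gr$total)),
                 per_term = gr$per_term,
                 per_pixel_r = gr$per_pixel_r,
                 masks = gr$masks),
            class = "endo_loss_report")
}

train_step <- function(batch, nets, cfg, opt = NULL, bootstrap = FALSE) {
  if (is.null(opt)) opt <- make_optimizer(nets, cfg)
  rep <- train_forward_backward(batch, nets, cfg, bootstrap = bootstrap)
  adam_step(opt)
  masks <- rep$masks
  rep$masks <- NULL
  attr(rep, "opt") <- opt
  attr(rep, "masks") <- masks
  rep
}

# ---- data plumbing ----

# normalize fit() input to list(frames = list of pixel arrays, K = intrinsics)
as_training_set <- function(data) {
  if (is.character(data)) {
    sq <- read_sequence(data)
    return(list(frames = lapply(sq$frames, frame_pixels), K = sq$K))
  }
  if (is.list(data) && length(data) && inherits(data[[1]], "endo_rendered")) {
    return(list(frames = lapply(data, function(f) f$frame$pixels),
                K = data[[1]]$K))
  }
  if (is.list(data) && !is.null(data$frames)) {
    return(list(frames = lapply(data$frames, frame_pixels), K = data$K))
  }
  stop("data must be a sequence directory, a rendered sequence, or ",
       "list(frames=, K=)")
}

#' Fit the self-supervised depth + decomposition model
#'
#' Trains the three networks on a monocular frame sequence with the
#' photometric reprojection objective. Specular-free supervision images are
#' precomputed (and cached) once per frame; training then iterates over
#' shuffled target/source triplets for `cfg$epochs` epochs. Fully seeded:
#' two runs with the same config and data produce identical loss logs.
#'
#' @param data a sequence directory (see [read_sequence()]), the result of
#'   [render_sequence()], or `list(frames=, K=)`.
#' @param cfg `endo_train_config`.
#' @return object of class `endo_model` with the trained networks, config,
#'   intrinsics and the per-step loss log (`$log`).
#' @export
depth_fit <- function(data, cfg = train_config()) {
  ts <- as_training_set(data)
  if (is.null(ts$K)) stop("training data carries no intrinsics")
  n <- length(ts$frames)
  if (n < 3) stop("need at least 3 frames")
  set.seed(cfg$seed)
  nets <- endo_networks(cfg$preset, seed = cfg$seed)
  cache_dir <- cfg$cache_dir %||% file.path(tempdir(), "endodepth-cache")
  rems <- vector("list", n)
  if (cfg$use_inpainting) {
    for (i in seq_len(n)) {
      pp <- preprocess_frame(endo_frame(ts$frames[[i]], frame_id = i - 1L),
                             cache_dir = cache_dir)
      rems[[i]] <- pp$I_rem$pixels
    }
  } else {
    rems <- ts$frames
  }
  offs <- cfg$source_offsets
  targets <- which(vapply(seq_len(n), function(t)
    all(t + offs >= 1 & t + offs <= n), logical(1)))
  if (!length(targets)) stop("no valid target frames for the source offsets")
  opt <- make_optimizer(nets, cfg)
  bs <- max(1L, cfg$batch_size)
  steps_per_ep <- ceiling(length(targets) / bs)
  planned <- min(cfg$epochs * steps_per_ep, cfg$max_steps)
  decay_at <- ceiling(cfg$lr_decay_frac * planned)
  log <- list()
  step <- 0L
  done <- FALSE
  for (ep in seq_len(cfg$epochs)) {
    if (done) break
    ord <- sample(targets)
    groups <- split(ord, ceiling(seq_along(ord) / bs))
    for (grp in groups) {
      step <- step + 1L
      if (step > cfg$max_steps) { done <- TRUE; break }
      if (step == decay_at) opt$scale <- opt$scale * cfg$lr_decay_factor
      totals <- c()
      terms <- NULL
      for (t in grp) {
        batch <- list(target = ts$frames[[t]],
                      sources = lapply(offs, function(o) ts$frames[[t + o]]),
                      target_rem = rems[[t]],
                      sources_rem = lapply(offs, function(o) rems[[t + o]]),
                      K = ts$K)
        rep <- train_forward_backward(batch, nets, cfg,
                                      bootstrap = step <= cfg$bootstrap_steps)
        totals <- c(totals, rep$total)
        terms <- if (is.null(terms)) unlist(rep$per_term)
                 else terms + unlist(rep$per_term)
      }
      if (length(grp) > 1L) {
        for (p in opt$params) if (!is.null(p$g)) p$g <- p$g / length(grp)
      }
      adam_step(opt)
      log[[length(log) + 1L]] <- c(step = step, epoch = ep,
                                   total = mean(totals), terms / length(grp))
    }
  }
  log <- as.data.frame(do.call(rbind, log))
  if (!is.null(cfg$log_csv)) utils::write.csv(log, cfg$log_csv, row.names = FALSE)
  structure(list(nets = nets, cfg = cfg, K = ts$K, log = log,
                 n_frames = n, resolution = dim(ts$frames[[1]])[1:2]),
            class = "endo_model")
}

# ---- inference ----

#' Decompose a single frame and estimate its depth
#'
#' One forward pass of the depth and decomposition networks. The specular
#' component is recovered at inference time as the residual between the
#' image and its diffuse reconstruction, binarized on the 8-bit scale at
#' `threshold` (default 50).
#'
#' @param I `endo_frame` or array.
#' @param nets `endo_networks` (or an `endo_model`).
#' @param cfg `endo_train_config` (taken from the model if one is given).
#' @param threshold 8-bit binarization threshold for the specular mask.
#' @return object of class `endo_inference`: list with `A`, `S`, `D`
#'   (`endo_depth`), `AS`, `residual` (continuous channel-max residual) and
#'   `M_binary`.
#' @export
infer_frame <- function(I, nets, cfg = NULL, threshold = 50) {
  if (inherits(nets, "endo_model")) {
    cfg <- cfg %||% nets$cfg
    nets <- nets$nets
  }
  cfg <- cfg %||% train_config()
  px <- frame_pixels(I)
  dec <- decompose_forward(nets, px)
  A <- vof(dec$A); S <- vof(dec$S)
  AS <- pmin(pmax(A * bc_channels(S, 3L), 0), 1)
  D <- vof(depth_forward(nets, px, cfg$d_min, cfg$d_max))
  residual <- channel_max(pmax(px - AS, 0))
  structure(list(A = A, S = S, D = depth_map(D[, , 1]), AS = AS,
                 residual = residual,
                 M_binary = binarize_residual(px, AS, threshold)),
            class = "endo_inference")
}

#' @export
print.endo_inference <- function(x, ...) {
  cat(sprintf("<endo_inference: depth [%.2f, %.2f], specular cover %.2f%%>\n",
              min(x$D$values), max(x$D$values), 100 * mean(x$M_binary)))
  invisible(x)
}

# ---- model S3 interface ----

#' @export
print.endo_model <- function(x, ...) {
  cat(sprintf("<endo_model: %s nets, %d frames @ %dx%d, %d steps, final loss %.4f>\n",
              x$nets$preset, x$n_frames, x$resolution[1], x$resolution[2],
              nrow(x$log), x$log$total[nrow(x$log)]))
  invisible(x)
}

#' @export
summary.endo_model <- function(object, ...) {
  lg <- object$log
  cat("Self-supervised depth + light decomposition model\n")
  cat(sprintf("  preset: %s   seed: %d   epochs trained: %d   steps: %d\n",
              object$nets$preset, object$cfg$seed, max(lg$epoch), nrow(lg)))
  cat(sprintf("  inpainting module: %s   static auto-mask: %s\n",
              object$cfg$use_inpainting, object$cfg$use_automask))
  cat(sprintf("  depth range: [%.2f, %.2f] scene units\n",
              object$cfg$d_min, object$cfg$d_max))
  cat(sprintf("  loss: %.4f (first) -> %.4f (last)\n",
              lg$total[1], lg$total[nrow(lg)]))
  invisible(object)
}

#' Predict on new frames
#'
#' @param object `endo_model`.
#' @param newdata an `endo_frame`, pixel array, or list of them.
#' @param ... unused.
#' @return an `endo_inference`, or a list of them.
#' @export
predict.endo_model <- function(object, newdata, ...) {
  if (is.list(newdata) && !inherits(newdata, "endo_frame") &&
      is.null(dim(newdata))) {
    return(lapply(newdata, function(f) infer_frame(f, object)))
  }
  infer_frame(newdata, object)
}

#' @export
plot.endo_model <- function(x, ...) {
  graphics::plot(x$log$step, x$log$total, type = "l", xlab = "step",
                 ylab = "total loss", main = "training loss", ...)
  invisible(x)
}

#' Save / load a trained model (checkpoint round-trip is bitwise)
#' @param model `endo_model`.
#' @param path `.rds` checkpoint path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "endo_model"))
  m
}
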