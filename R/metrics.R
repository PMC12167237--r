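# Depth evaluation: standard monocular error metrics after median scaling
# (monocular depth is scale-ambiguous, so predictions are rescaled by
# median(gt)/median(pred) before comparison), computed per image and then
# averaged across images; plus the specularity-surrounding metric (SSM),
# the percentage of specular regions whose mean depth stays close to that
# of their immediate surroundings — a smoothness-across-speculars score for
# data without ground truth.

#' Median-scale a predicted depth map to the ground truth
#'
#' Multiplies the prediction by `median(gt)/median(pred)` over the valid
#' pixels, so that `pred = c * gt` is mapped back to `gt` exactly for any
#' `c > 0`.
#'
#' @param pred,gt `endo_depth` or matrices.
#' @param valid optional logical/0-1 matrix of pixels to use.
#' @return scaled prediction (matrix).
#' @export
median_scale <- function(pred, gt, valid = NULL) {
  p <- depth_values(pred); g <- depth_values(gt)
  if (!all(dim(p) == dim(g))) stop("pred and gt sizes disagree")
  v <- if (is.null(valid)) rep(TRUE, length(g)) else as.logical(valid)
  if (!any(v)) stop("no valid pixels for median scaling")
  if (any(g[v] <= 0)) stop("ground truth must be positive on valid pixels")
  p * (stats::median(g[v]) / stats::median(p[v]))
}

#' Direct depth error metrics
#'
#' Standard monocular depth metrics over the valid pixels of one image:
#' `MAE`, `MedAE`, `RMSE` (scene units), `RMSE_log`, `Abs_Rel`
#' (`mean |e|/gt`), `Sq_Rel` (`mean e^2/gt`) and the threshold accuracies
#' `delta_k` = fraction with `max(pred/gt, gt/pred) < 1.25^k`, k = 1, 2, 3.
#' The input is expected to be median-scaled already.
#'
#' @param pred,gt `endo_depth` or matrices (positive on valid pixels).
#' @param valid optional mask.
#' @return object of class `endo_depth_metrics` (a named list of scalars).
#' @export
depth_metrics <- function(pred, gt, valid = NULL) {
  p <- depth_values(pred); g <- depth_values(gt)
  if (!all(dim(p) == dim(g))) stop("pred and gt sizes disagree")
  v <- if (is.null(valid)) rep(TRUE, length(g)) else as.logical(valid)
  if (!any(v)) stop("no valid pixels")
  p <- p[v]; g <- g[v]
  if (any(p <= 0) || any(g <= 0)) stop("depths must be positive for log/ratio metrics")
  e <- p - g
  ratio <- pmax(p / g, g / p)
  structure(list(
    MAE = mean(abs(e)),
    MedAE = stats::median(abs(e)),
    RMSE = sqrt(mean(e^2)),
    RMSE_log = sqrt(mean((log(p) - log(g))^2)),
    Abs_Rel = mean(abs(e) / g),
    Sq_Rel = mean(e^2 / g),
    delta1 = mean(ratio < 1.25),
    delta2 = mean(ratio < 1.25^2),
    delta3 = mean(ratio < 1.25^3),
    n = sum(v)
  ), class = "endo_depth_metrics")
}

#' @export
print.endo_depth_metrics <- function(x, ...) {
  cat(sprintf(paste0("MAE %.4f  MedAE %.4f  RMSE %.4f  RMSE_log %.4f  ",
                     "Abs_Rel %.4f  Sq_Rel %.4f\n",
                     "delta<1.25 %.4f  delta<1.25^2 %.4f  delta<1.25^3 %.4f  (n=%d)\n"),
              x$MAE, x$MedAE, x$RMSE, x$RMSE_log, x$Abs_Rel, x$Sq_Rel,
              x$delta1, x$delta2, x$delta3, x$n))
  invisible(x)
}

#' Sequence-level depth evaluation
#'
#' Applies median scaling and [depth_metrics()] per image, then averages
#' each metric across images (not pooled over pixels).
#'
#' @param preds,gts lists of depth maps/matrices of equal length.
#' @param border pixels to crop from every edge before evaluation.
#' @return list with `mean` (averaged `endo_depth_metrics`) and `per_image`.
#' @export
evaluate_depth_sequence <- function(preds, gts, border = 0L) {
  stopifnot(length(preds) == length(gts), length(preds) >= 1)
  per <- lapply(seq_along(preds), function(i) {
    p <- depth_values(preds[[i]]); g <- depth_values(gts[[i]])
    if (border > 0) {
      H <- nrow(p); W <- ncol(p)
      rs <- (border + 1):(H - border); cs <- (border + 1):(W - border)
      p <- p[rs, cs]; g <- g[rs, cs]
    }
    valid <- g > 0
    depth_metrics(median_scale(p, g, valid), g, valid)
  })
  keys <- setdiff(names(per[[1]]), "n")
  avg <- lapply(keys, function(k) mean(vapply(per, function(m) m[[k]], numeric(1))))
  names(avg) <- keys
  avg$n <- sum(vapply(per, function(m) m$n, numeric(1)))
  list(mean = structure(avg, class = "endo_depth_metrics"), per_image = per)
}

#' Specularity-surrounding metric (SSM)
#'
#' For every detected specular region, compares the mean depth inside the
#' region (`Mean_spec`) with the mean depth of its surroundings
#' (`Mean_surr`): the region's bounding box grown by `margin` pixels, minus
#' the region itself. The region counts as smooth when
#' `|Mean_spec - Mean_surr| <= tau * Mean_surr` (a relative criterion, so
#' the score is invariant to global depth rescaling). SSM is the percentage
#' of smooth regions; an image without regions returns `NA` and should be
#' excluded from dataset averages.
#'
#' @param depth `endo_depth` or matrix (the predicted depth under test).
#' @param regions `endo_specular_regions` from [segment_speculars()] on the
#'   same image.
#' @param tau relative closeness tolerance, default 0.1.
#' @param margin bounding-box growth in pixels, default 5.
#' @return object of class `endo_ssm`: list with `ssm_percent` (or `NA`),
#'   `n_regions`, and `per_region` (rows `mean_spec`, `mean_surr`,
#'   `smooth`).
#' @export
ssm_metric <- function(depth, regions, tau = 0.1, margin = 5L) {
  D <- depth_values(depth)
  H <- nrow(D); W <- ncol(D)
  stopifnot(inherits(regions, "endo_specular_regions"))
  per <- list()
  for (i in seq_along(regions$regions)) {
    rg <- regions$regions[[i]]
    bb <- rg$bbox
    r0 <- max(bb["r0"] - margin, 0); r1 <- min(bb["r1"] + margin, H)
    c0 <- max(bb["c0"] - margin, 0); c1 <- min(bb["c1"] + margin, W)
    sel <- matrix(FALSE, H, W)
    sel[(r0 + 1):r1, (c0 + 1):c1] <- TRUE
    sel[rg$pixels] <- FALSE
    # exclude all specular pixels (any region) from the surround
    sel[regions$mask > 0] <- FALSE
    if (!any(sel)) next
    mean_spec <- mean(D[rg$pixels])
    mean_surr <- mean(D[sel])
    per[[length(per) + 1L]] <- c(mean_spec = mean_spec, mean_surr = mean_surr,
                                 smooth = as.numeric(
                                   abs(mean_spec - mean_surr) <= tau * mean_surr))
  }
  n <- length(per)
  ssm <- if (n == 0) NA_real_ else 100 * mean(vapply(per, `[[`, numeric(1), "smooth"))
  structure(list(ssm_percent = ssm, n_regions = n,
                 per_region = if (n) do.call(rbind, per) else NULL,
                 tau = tau, margin = margin),
            class = "endo_ssm")
}

#' @export
print.endo_ssm <- function(x, ...) {
  if (is.na(x$ssm_percent)) {
    cat("<endo_ssm: no specular regions (undefined)>\n")
  } else {
    cat(sprintf("<endo_ssm: %.1f%% smooth of %d region(s), tau=%.2f margin=%d>\n",
                x$ssm_percent, x$n_regions, x$tau, x$margin))
  }
  invisible(x)
}
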