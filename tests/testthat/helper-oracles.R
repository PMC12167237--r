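# Independent reference implementations used as oracles: everything here is
# a deliberately naive scalar loop, kept free of the package's vectorized
# code paths.

# per-pixel pinhole reprojection, one pixel at a time
oracle_reproject <- function(D, K, tf) {
  H <- nrow(D); W <- ncol(D)
  u <- matrix(NA_real_, H, W); v <- matrix(NA_real_, H, W)
  z <- matrix(NA_real_, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      x <- c((c - 1 - K$cx) / K$fx, (r - 1 - K$cy) / K$fy, 1) * D[r, c]
      y <- as.numeric(tf$R %*% x + tf$t)
      z[r, c] <- y[3]
      if (y[3] > 1e-8) {
        u[r, c] <- K$fx * y[1] / y[3] + K$cx
        v[r, c] <- K$fy * y[2] / y[3] + K$cy
      }
    }
  }
  list(u = u, v = v, z = z)
}

# scalar bilinear sampling with zero padding (validity = 2x2 support inside)
oracle_warp <- function(src, D, K, tf) {
  H <- nrow(D); W <- ncol(D)
  C <- dim(src)[3]
  rp <- oracle_reproject(D, K, tf)
  out <- array(0, dim = c(H, W, C))
  valid <- matrix(0, H, W)
  for (r in seq_len(H)) {
    for (c in seq_len(W)) {
      u <- rp$u[r, c]; v <- rp$v[r, c]
      if (is.na(u) || is.na(v)) next
      if (u < 0 || u > W - 1 || v < 0 || v > H - 1) next
      x0 <- min(max(floor(u), 0), W - 2); y0 <- min(max(floor(v), 0), H - 2)
      fx <- u - x0; fy <- v - y0
      for (ch in seq_len(C)) {
        v00 <- src[y0 + 1, x0 + 1, ch]; v10 <- src[y0 + 1, x0 + 2, ch]
        v01 <- src[y0 + 2, x0 + 1, ch]; v11 <- src[y0 + 2, x0 + 2, ch]
        out[r, c, ch] <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
          (1 - fx) * fy * v01 + fx * fy * v11
      }
      valid[r, c] <- 1
    }
  }
  list(warped = out, valid = valid)
}

# scalar-loop depth metrics
oracle_depth_metrics <- function(p, g) {
  n <- length(p)
  ae <- se <- le <- ar <- sr <- numeric(n)
  d1 <- d2 <- d3 <- logical(n)
  for (i in seq_len(n)) {
    e <- p[i] - g[i]
    ae[i] <- abs(e); se[i] <- e^2
    le[i] <- (log(p[i]) - log(g[i]))^2
    ar[i] <- abs(e) / g[i]; sr[i] <- e^2 / g[i]
    rt <- max(p[i] / g[i], g[i] / p[i])
    d1[i] <- rt < 1.25; d2[i] <- rt < 1.25^2; d3[i] <- rt < 1.25^3
  }
  list(MAE = mean(ae), MedAE = median(ae), RMSE = sqrt(mean(se)),
       RMSE_log = sqrt(mean(le)), Abs_Rel = mean(ar), Sq_Rel = mean(sr),
       delta1 = mean(d1), delta2 = mean(d2), delta3 = mean(d3))
}

# closed-form SSIM for two constant images (variance terms vanish)
oracle_ssim_const <- function(a, b, C1 = 0.01^2, C2 = 0.03^2) {
  ((2 * a * b + C1) * C2) / ((a^2 + b^2 + C1) * C2)
}

# scalar ray/cylinder intersection: camera at o (inside), unnormalized
# camera ray d (z component 1 in camera frame); returns the ray parameter,
# i.e. the z-depth
oracle_ray_cylinder <- function(o, d, radius) {
  a <- d[1]^2 + d[2]^2
  b <- 2 * (o[1] * d[1] + o[2] * d[2])
  cc <- o[1]^2 + o[2]^2 - radius^2
  if (a < 1e-14) return(Inf)
  (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
}

iou_masks <- function(a, b) {
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

random_rotation <- function(max_deg) {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, max_deg * pi / 180)
  pose_vector_to_transform(c(ax * ang, 0, 0, 0))$R
}
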