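# Rigid camera motions (SE(3)): construction, validation, composition, and
# the axis-angle exponential / logarithm used by the pose network.

#' Rigid transform between camera frames
#'
#' `T_t_to_s` maps target-camera coordinates into source-camera coordinates:
#' `X_s = R X_t + t`.
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1, checked to
#'   1e-6).
#' @param translation length-3 numeric vector, scene units.
#' @return object of class `endo_transform` with fields `R` and `t`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation is not orthonormal (R'R != I beyond 1e-6)")
  }
  if (abs(det(rotation) - 1) > 1e-6) stop("rotation must have det +1")
  structure(list(R = rotation, t = translation), class = "endo_transform")
}

#' @export
print.endo_transform <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$R)) - 1) / 2, -1), 1)) * 180 / pi
  cat(sprintf("<endo_transform: rotation %.3f deg, |t| = %.4f>\n",
              ang, sqrt(sum(x$t^2))))
  invisible(x)
}

#' Invert a rigid transform
#' @param tf `endo_transform`.
#' @return the inverse `endo_transform`.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$R), -as.numeric(t(tf$R) %*% tf$t))
}

#' Compose rigid transforms (`a` applied after `b`)
#' @param a,b `endo_transform`s.
#' @return `endo_transform` equal to `a %*% b`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

# skew-symmetric cross-product matrix
skew3 <- function(w) {
  matrix(c(0, w[3], -w[2],
           -w[3], 0, w[1],
           w[2], -w[1], 0), 3, 3)
}

#' Axis-angle + translation 6-vector to rigid transform
#'
#' First three entries are the axis-angle rotation (Rodrigues exponential
#' map), last three the translation. The zero vector maps to the identity.
#'
#' @param v numeric length-6 vector.
#' @return `endo_transform`.
#' @export
pose_vector_to_transform <- function(v) {
  v <- as.numeric(v)
  stopifnot(length(v) == 6, all(is.finite(v)))
  w <- v[1:3]
  th <- sqrt(sum(w^2))
  if (th < 1e-12) {
    R <- diag(3)
  } else {
    Wx <- skew3(w)
    # sin(th)/th and 2*sin^2(th/2)/th^2 are cancellation-free
    A <- sin(th) / th
    B <- 2 * sin(th / 2)^2 / th^2
    R <- diag(3) + A * Wx + B * (Wx %*% Wx)
  }
  rigid_transform(R, v[4:6])
}

#' Rigid transform to axis-angle + translation 6-vector (log map)
#'
#' Inverse of [pose_vector_to_transform()] for rotation angles below pi.
#' @param tf `endo_transform`.
#' @return numeric length-6 vector.
#' @export
transform_to_pose_vector <- function(tf) {
  R <- tf$R
  cth <- pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1)
  th <- acos(cth)
  if (th < 1e-10) {
    w <- c(0, 0, 0)
  } else {
    w <- th / (2 * sin(th)) * c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  }
  c(w, tf$t)
}

# Differentiable Rodrigues map: 6-vector node -> list(R = 3x3 node, t = 3 node).
# Mirrors pose_vector_to_transform with tape ops; the small-angle branch uses
# the series A ~ 1 - th^2/6, B ~ 1/2 - th^2/24 so gradients stay finite at 0.
nd_pose_to_Rt <- function(v6) {
  w1 <- nd_index(v6, 1L); w2 <- nd_index(v6, 2L); w3 <- nd_index(v6, 3L)
  t3 <- list(nd_index(v6, 4L), nd_index(v6, 5L), nd_index(v6, 6L))
  th2 <- nd_add(nd_add(nd_mul(w1, w1), nd_mul(w2, w2)), nd_mul(w3, w3))
  th2v <- as.numeric(vof(th2))
  if (th2v < 1e-16) {
    A <- nd_affine(th2, -1 / 6, 1)          # sin(th)/th
    B <- nd_affine(th2, -1 / 24, 0.5)       # (1-cos(th))/th^2
  } else {
    th <- nd_sqrt(th2)
    A <- nd_div(nd_sin(th), th)
    half <- nd_affine(th, 0.5)
    s2 <- nd_sin(half)
    B <- nd_div(nd_affine(nd_mul(s2, s2), 2), th2)
  }
  # R = I + A*[w]x + B*[w]x^2 expanded entrywise
  w11 <- nd_mul(w1, w1); w22 <- nd_mul(w2, w2); w33 <- nd_mul(w3, w3)
  w12 <- nd_mul(w1, w2); w13 <- nd_mul(w1, w3); w23 <- nd_mul(w2, w3)
  r11 <- nd_sadd(nd_neg(nd_mul(B, nd_add(w22, w33))), 1)
  r22 <- nd_sadd(nd_neg(nd_mul(B, nd_add(w11, w33))), 1)
  r33 <- nd_sadd(nd_neg(nd_mul(B, nd_add(w11, w22))), 1)
  r12 <- nd_sub(nd_mul(B, w12), nd_mul(A, w3))
  r21 <- nd_add(nd_mul(B, w12), nd_mul(A, w3))
  r13 <- nd_add(nd_mul(B, w13), nd_mul(A, w2))
  r31 <- nd_sub(nd_mul(B, w13), nd_mul(A, w2))
  r23 <- nd_sub(nd_mul(B, w23), nd_mul(A, w1))
  r32 <- nd_add(nd_mul(B, w23), nd_mul(A, w1))
  list(R = list(r11, r12, r13, r21, r22, r23, r31, r32, r33),  # row-major
       t = t3)
}
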