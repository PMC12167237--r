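# Reverse-mode automatic differentiation over dense arrays.
#
# A node ("nd") is an environment holding a value `v`, an accumulated gradient
# `g`, the parent nodes and a backward closure. Ops accept either nodes or
# plain arrays; when the tape is off (the default) every op degenerates to
# plain array arithmetic and returns a plain array, so the same loss code
# serves both the numeric user-facing API and the training loop.

.ad <- new.env(parent = emptyenv())
.ad$on <- FALSE
.ad$nodes <- NULL
.ad$n <- 0L

#' Run an expression with gradient recording enabled
#'
#' Starts a fresh tape, evaluates `expr`, and returns its result (typically a
#' scalar loss node on which [ad_backward()] has been or will be called).
#' Recording is always switched off afterwards.
#'
#' @param expr expression building the computation out of `nd_*` ops.
#' @return the value of `expr`.
#' @keywords internal
with_tape <- function(expr) {
  .ad$on <- TRUE
  .ad$nodes <- vector("list", 256L)
  .ad$n <- 0L
  on.exit({
    .ad$on <- FALSE
    .ad$nodes <- NULL
    .ad$n <- 0L
  })
  expr
}

is_nd <- function(x) inherits(x, "nd")

#' @keywords internal
vof <- function(x) if (is_nd(x)) x$v else x

nd_requires <- function(x) is_nd(x) && isTRUE(x$req)

new_nd <- function(v, req = FALSE) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$g <- NULL
  e$req <- req
  e$bk <- NULL
  class(e) <- "nd"
  e
}

record <- function(node) {
  .ad$n <- .ad$n + 1L
  if (.ad$n > length(.ad$nodes)) {
    length(.ad$nodes) <- 2L * length(.ad$nodes)
  }
  .ad$nodes[[.ad$n]] <- node
  node
}

#' Create a trainable leaf (parameter) node
#' @keywords internal
nd_param <- function(v) new_nd(v, req = TRUE)

# Accumulate gradient `g` into node `p` (no-op for plain arrays / non-req nodes).
acc_grad <- function(p, g) {
  if (!nd_requires(p)) return(invisible(NULL))
  p$g <- if (is.null(p$g)) g else p$g + g
  invisible(NULL)
}

# Build an op result. `bk` is called with the output gradient and must
# acc_grad() into the parents it closes over.
mkop <- function(v, parents, bk) {
  if (!.ad$on) return(v)
  req <- FALSE
  for (p in parents) if (nd_requires(p)) { req <- TRUE; break }
  if (!req) return(v)
  node <- new_nd(v, req = TRUE)
  node$bk <- bk
  record(node)
}

#' Backpropagate from a scalar node
#'
#' Seeds the gradient of `root` with 1 and sweeps the tape in reverse
#' creation order, accumulating gradients into every parameter node.
#' @keywords internal
ad_backward <- function(root) {
  stopifnot(is_nd(root), length(root$v) == 1L)
  root$g <- 1
  if (.ad$n == 0L) return(invisible(NULL))
  for (i in seq.int(.ad$n, 1L)) {
    node <- .ad$nodes[[i]]
    if (!is.null(node$g) && !is.null(node$bk)) node$bk(node$g)
  }
  invisible(NULL)
}

#' Detach a value from the tape
#' @keywords internal
nd_detach <- function(x) vof(x)

# ---- elementwise arithmetic ----

nd_add <- function(a, b) {
  va <- vof(a); vb <- vof(b)
  mkop(va + vb, list(a, b), function(g) { acc_grad(a, g); acc_grad(b, g) })
}

nd_sub <- function(a, b) {
  va <- vof(a); vb <- vof(b)
  mkop(va - vb, list(a, b), function(g) { acc_grad(a, g); acc_grad(b, -g) })
}

nd_mul <- function(a, b) {
  va <- vof(a); vb <- vof(b)
  mkop(va * vb, list(a, b), function(g) { acc_grad(a, g * vb); acc_grad(b, g * va) })
}

nd_div <- function(a, b) {
  va <- vof(a); vb <- vof(b)
  mkop(va / vb, list(a, b), function(g) {
    acc_grad(a, g / vb)
    acc_grad(b, -g * va / (vb * vb))
  })
}

nd_neg <- function(a) {
  va <- vof(a)
  mkop(-va, list(a), function(g) acc_grad(a, -g))
}

# a*x + b with plain-numeric a, b (affine reparameterization, e.g. intrinsics).
nd_affine <- function(x, a, b = 0) {
  vx <- vof(x)
  mkop(a * vx + b, list(x), function(g) acc_grad(x, a * g))
}

# map (*) scalar-node and map (+) scalar-node; `s` has length 1.
nd_smul <- function(x, s) {
  vx <- vof(x); vs <- as.numeric(vof(s))
  mkop(vx * vs, list(x, s), function(g) {
    acc_grad(x, g * vs)
    acc_grad(s, sum(g * vx))
  })
}

nd_sadd <- function(x, s) {
  vx <- vof(x); vs <- as.numeric(vof(s))
  mkop(vx + vs, list(x, s), function(g) {
    acc_grad(x, g)
    acc_grad(s, sum(g))
  })
}

# ---- elementwise nonlinearities ----

nd_abs <- function(a) {
  va <- vof(a)
  mkop(abs(va), list(a), function(g) acc_grad(a, g * sign(va)))
}

nd_exp <- function(a) {
  y <- exp(vof(a))
  mkop(y, list(a), function(g) acc_grad(a, g * y))
}

nd_log <- function(a) {
  va <- vof(a)
  mkop(log(va), list(a), function(g) acc_grad(a, g / va))
}

nd_sqrt <- function(a) {
  y <- sqrt(vof(a))
  mkop(y, list(a), function(g) acc_grad(a, g / (2 * y)))
}

nd_sin <- function(a) {
  va <- vof(a)
  mkop(sin(va), list(a), function(g) acc_grad(a, g * cos(va)))
}

nd_cos <- function(a) {
  va <- vof(a)
  mkop(cos(va), list(a), function(g) acc_grad(a, -g * sin(va)))
}

nd_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-vof(a)))
  mkop(y, list(a), function(g) acc_grad(a, g * y * (1 - y)))
}

# log(1 + exp(x)), numerically stable.
nd_softplus <- function(a) {
  va <- vof(a)
  y <- ifelse(va > 30, va, log1p(exp(pmin(va, 30))))
  if (!is.null(dim(va))) dim(y) <- dim(va)
  mkop(y, list(a), function(g) acc_grad(a, g / (1 + exp(-va))))
}

nd_elu <- function(a) {
  va <- vof(a)
  y <- ifelse(va > 0, va, expm1(va))
  if (!is.null(dim(va))) dim(y) <- dim(va)
  mkop(y, list(a), function(g) acc_grad(a, g * ifelse(va > 0, 1, exp(va))))
}

# clamp with zero gradient outside [lo, hi]
nd_clamp <- function(a, lo, hi) {
  va <- vof(a)
  y <- pmin(pmax(va, lo), hi)
  if (!is.null(dim(va))) dim(y) <- dim(va)
  inside <- (va >= lo) & (va <= hi)
  mkop(y, list(a), function(g) acc_grad(a, g * inside))
}

nd_pow_const <- function(a, p) {
  va <- vof(a)
  mkop(va^p, list(a), function(g) acc_grad(a, g * p * va^(p - 1)))
}

# elementwise minimum; gradient follows the argmin (ties -> first arg)
nd_min2 <- function(a, b) {
  va <- vof(a); vb <- vof(b)
  sel <- va <= vb
  y <- ifelse(sel, va, vb)
  if (!is.null(dim(va))) dim(y) <- dim(va)
  mkop(y, list(a, b), function(g) {
    acc_grad(a, g * sel)
    acc_grad(b, g * !sel)
  })
}

# ---- reductions ----

nd_sum <- function(a) {
  va <- vof(a)
  mkop(sum(va), list(a), function(g) acc_grad(a, array(g, dim(va))))
}

nd_mean <- function(a) {
  va <- vof(a)
  n <- length(va)
  mkop(sum(va) / n, list(a), function(g) acc_grad(a, array(g / n, dim(va))))
}

# Mean of `a` over pixels where plain-array mask m == 1. Mask values gate the
# gradient; an empty mask yields 0 (the caller is expected to warn).
nd_masked_mean <- function(a, m) {
  va <- vof(a)
  m <- vof(m)
  n <- sum(m)
  if (n == 0) return(mkop(0, list(a), function(g) acc_grad(a, array(0, dim(va)))))
  mkop(sum(va * m) / n, list(a), function(g) acc_grad(a, array(g, dim(va)) * m / n))
}

# ---- shape ops (H x W x C arrays) ----

# replicate a 1-channel map to k channels
nd_repc <- function(a, k) {
  va <- vof(a)
  d <- dim(va)
  stopifnot(length(d) == 3L, d[3] == 1L)
  y <- array(va, dim = c(d[1], d[2], k))
  mkop(y, list(a), function(g) {
    gs <- g[, , 1, drop = FALSE]
    if (k > 1) for (j in 2:k) gs <- gs + g[, , j, drop = FALSE]
    acc_grad(a, gs)
  })
}

# mean over channels -> H x W x 1
nd_cmean <- function(a) {
  va <- vof(a)
  d <- dim(va)
  k <- d[3]
  y <- va[, , 1, drop = FALSE]
  if (k > 1) for (j in 2:k) y <- y + va[, , j, drop = FALSE]
  y <- y / k
  mkop(y, list(a), function(g) acc_grad(a, array(g / k, dim = d)))
}

nd_slice_c <- function(a, j) {
  va <- vof(a)
  d <- dim(va)
  y <- va[, , j, drop = FALSE]
  mkop(y, list(a), function(g) {
    gg <- array(0, dim = d)
    gg[, , j] <- g
    acc_grad(a, gg)
  })
}

nd_concat_c <- function(lst) {
  vs <- lapply(lst, vof)
  ks <- vapply(vs, function(x) dim(x)[3], numeric(1))
  d1 <- dim(vs[[1]])
  y <- array(unlist(vs, use.names = FALSE), dim = c(d1[1], d1[2], sum(ks)))
  ends <- cumsum(ks)
  starts <- c(1, head(ends, -1) + 1)
  mkop(y, lst, function(g) {
    for (i in seq_along(lst)) {
      acc_grad(lst[[i]], g[, , starts[i]:ends[i], drop = FALSE])
    }
  })
}

# extract one scalar from a small vector/matrix node
nd_index <- function(a, i) {
  va <- vof(a)
  mkop(va[[i]], list(a), function(g) {
    gg <- array(0, dim = if (is.null(dim(va))) length(va) else dim(va))
    gg[[i]] <- g
    acc_grad(a, gg)
  })
}

# assemble scalars (nodes or numerics) into an array of dim `d`
nd_stack <- function(lst, d) {
  v <- array(vapply(lst, function(x) as.numeric(vof(x)), numeric(1)), dim = d)
  mkop(v, lst, function(g) {
    for (i in seq_along(lst)) acc_grad(lst[[i]], g[[i]])
  })
}

# ---- linear algebra ----

nd_matmul <- function(a, b) {
  va <- vof(a); vb <- vof(b)
  mkop(va %*% vb, list(a, b), function(g) {
    acc_grad(a, g %*% t(vb))
    acc_grad(b, crossprod(va, g))
  })
}

# add a length-K bias to every row of an N x K matrix
nd_addbias <- function(x, b) {
  vx <- vof(x); vb <- vof(b)
  mkop(sweep(vx, 2, vb, "+"), list(x, b), function(g) {
    acc_grad(x, g)
    acc_grad(b, colSums(g))
  })
}
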