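#' @useDynLib spixelseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---------------------------------------------------------------------------
# Tape-based reverse-mode autodiff over plain R arrays.
#
# The package trains three convolutional networks on one CPU, so it carries a
# compact NN core rather than depending on an external deep-learning runtime.
# Tensors are environments holding `value` (an array), `grad`, and - when they
# participate in a recorded graph - `parents` plus a `backward` closure that
# maps the output gradient to parent gradients.  A global tape records ops in
# creation order; sx_backward() replays it in reverse.
# ---------------------------------------------------------------------------

.sx <- new.env(parent = emptyenv())
.sx$nodes <- list()
.sx$n <- 0L
.sx$recording <- TRUE

sx_tape_reset <- function() {
  .sx$nodes <- vector("list", 256L)
  .sx$n <- 0L
  invisible(NULL)
}

#' Evaluate an expression without recording gradients
#' @param expr expression to evaluate in inference mode
#' @return the value of `expr`
#' @keywords internal
sx_no_grad <- function(expr) {
  old <- .sx$recording
  .sx$recording <- FALSE
  on.exit(.sx$recording <- old)
  expr
}

sx_tensor <- function(value, requires_grad = FALSE) {
  t <- new.env(parent = emptyenv())
  t$value <- value
  t$grad <- NULL
  t$needs_grad <- requires_grad
  t$requires_grad <- requires_grad
  t$parents <- NULL
  t$backward <- NULL
  class(t) <- "sx_tensor"
  t
}

sx_const <- function(value) sx_tensor(value, requires_grad = FALSE)
sx_param <- function(value) sx_tensor(value, requires_grad = TRUE)

sx_op <- function(value, parents, backward) {
  t <- sx_tensor(value)
  t$needs_grad <- any(vapply(parents, function(p) isTRUE(p$needs_grad), TRUE))
  if (t$needs_grad && .sx$recording) {
    t$parents <- parents
    t$backward <- backward
    n <- .sx$n + 1L
    if (n > length(.sx$nodes)) .sx$nodes <- c(.sx$nodes, vector("list", length(.sx$nodes)))
    .sx$nodes[[n]] <- t
    .sx$n <- n
  }
  t
}

acc_grad <- function(p, g) {
  if (!isTRUE(p$needs_grad) || is.null(g)) return(invisible(NULL))
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

#' Run reverse-mode accumulation from a scalar loss
#' @param loss scalar `sx_tensor` produced on the current tape
#' @keywords internal
sx_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- 1
  if (.sx$n == 0L) return(invisible(NULL))
  for (i in seq(.sx$n, 1L)) {
    t <- .sx$nodes[[i]]
    if (is.null(t$grad) || is.null(t$backward)) next
    gs <- t$backward(t$grad)
    for (j in seq_along(t$parents)) acc_grad(t$parents[[j]], gs[[j]])
  }
  invisible(NULL)
}

sx_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# --- elementwise -----------------------------------------------------------

sx_add <- function(a, b) {
  if (is.numeric(b)) {
    return(sx_op(a$value + b, list(a), function(g) list(g)))
  }
  sx_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

sx_sub <- function(a, b) {
  if (is.numeric(b)) {
    return(sx_op(a$value - b, list(a), function(g) list(g)))
  }
  sx_op(a$value - b$value, list(a, b), function(g) list(g, -g))
}

sx_mul <- function(a, b) {
  if (is.numeric(b)) {
    return(sx_op(a$value * b, list(a), function(g) list(g * b)))
  }
  av <- a$value; bv <- b$value
  sx_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

sx_relu <- function(x) {
  xv <- x$value
  if (is.null(dim(xv))) {
    y <- xv
    y[xv < 0] <- 0
    return(sx_op(y, list(x), function(g) list(g * (xv > 0))))
  }
  sx_op(cpp_relu_forward(xv), list(x), function(g) {
    if (is.null(dim(g))) dim(g) <- dim(xv)
    list(cpp_relu_backward(g, xv))
  })
}

sx_sigmoid <- function(x) {
  y <- 1 / (1 + exp(-x$value))
  sx_op(y, list(x), function(g) list(g * y * (1 - y)))
}

sx_softplus <- function(x) {
  xv <- x$value
  y <- pmax(xv, 0) + log1p(exp(-abs(xv)))
  sx_op(y, list(x), function(g) list(g / (1 + exp(-xv))))
}

sx_log <- function(x) {
  xv <- x$value
  sx_op(log(xv), list(x), function(g) list(g / xv))
}

sx_sqrt <- function(x) {
  y <- sqrt(x$value)
  sx_op(y, list(x), function(g) list(g / (2 * y)))
}

# exact sqrt value with an eps-smoothed gradient so unsquared norms are
# finite to differentiate at zero
sx_sqrt_smooth <- function(x, eps = 1e-12) {
  xv <- x$value
  sx_op(sqrt(pmax(xv, 0)), list(x), function(g) list(g / (2 * sqrt(xv + eps))))
}

sx_clamp_min <- function(x, lo) {
  xv <- x$value
  sx_op(pmax(xv, lo), list(x), function(g) list(g * (xv > lo)))
}

# --- reductions ------------------------------------------------------------

sx_sum <- function(x) {
  d <- dim(x$value); n <- length(x$value)
  sx_op(sum(x$value), list(x), function(g) {
    gx <- rep(as.numeric(g), n)
    if (!is.null(d)) dim(gx) <- d
    list(gx)
  })
}

sx_mean <- function(x) sx_mul(sx_sum(x), 1 / length(x$value))

# --- matrix ops ------------------------------------------------------------

sx_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  sx_op(av %*% bv, list(a, b), function(g)
    list(g %*% t(bv), t(av) %*% g))
}

sx_transpose <- function(a) {
  sx_op(t(a$value), list(a), function(g) list(t(g)))
}

# y[i, ] = x[i, ] / v[i]    (v a column vector / length-nrow numeric tensor)
sx_div_rows <- function(x, v) {
  xv <- x$value; vv <- as.vector(v$value)
  y <- xv / vv
  sx_op(y, list(x, v), function(g) {
    gv <- -rowSums(g * xv) / vv^2
    list(g / vv, matrix(gv, ncol = 1))
  })
}

# add a length-ncol bias to every row of an (N x C) matrix
sx_bias_rows <- function(x, b) {
  bv <- as.vector(b$value)
  sx_op(sweep(x$value, 2L, bv, "+"), list(x, b), function(g)
    list(g, colSums(g)))
}

sx_row <- function(x, i) {
  d <- dim(x$value)
  sx_op(x$value[i, , drop = FALSE], list(x), function(g) {
    gx <- matrix(0, d[1], d[2])
    gx[i, ] <- g
    list(gx)
  })
}

# gather rows of a (P x k) matrix; idx may contain duplicates
sx_gather_rows <- function(x, idx) {
  d <- dim(x$value)
  sx_op(x$value[idx, , drop = FALSE], list(x), function(g) {
    gx <- matrix(0, d[1], d[2])
    rs <- rowsum(g, group = idx)
    gx[as.integer(rownames(rs)), ] <- gx[as.integer(rownames(rs)), ] + rs
    list(gx)
  })
}

# extract image n of an (H,W,C,N) tensor as a (C x H*W) matrix
# (columns follow R's column-major raster order)
sx_img_mat <- function(x, n) {
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]
  img <- x$value[, , , n, drop = FALSE]
  m <- t(matrix(img, H * W, C))
  sx_op(m, list(x), function(g) {
    gx <- array(0, d)
    gx[, , , n] <- array(t(g), c(H, W, C))
    list(gx)
  })
}

# --- softmaxes -------------------------------------------------------------

# softmax over dim 1 (every column sums to 1)
sx_softmax_cols <- function(x) {
  xv <- x$value
  e <- exp(sweep(xv, 2L, apply(xv, 2L, max), "-"))
  y <- sweep(e, 2L, colSums(e), "/")
  sx_op(y, list(x), function(g) {
    s <- colSums(g * y)
    list(y * sweep(g, 2L, s, "-"))
  })
}

# softmax over dim 2 (every row sums to 1)
sx_softmax_rows <- function(x) {
  xv <- x$value
  e <- exp(xv - apply(xv, 1L, max))
  y <- e / rowSums(e)
  sx_op(y, list(x), function(g) {
    s <- rowSums(g * y)
    list(y * (g - s))
  })
}

# per-pixel softmax over the channel axis of an (H,W,C,N) tensor
sx_softmax_channels <- function(x) {
  d <- dim(x$value)
  C <- d[3]
  m <- matrix(aperm(x$value, c(1, 2, 4, 3)), ncol = C)
  e <- exp(m - apply(m, 1L, max))
  ym <- e / rowSums(e)
  y <- aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  sx_op(y, list(x), function(g) {
    gm <- matrix(aperm(g, c(1, 2, 4, 3)), ncol = C)
    s <- rowSums(gm * ym)
    dz <- ym * (gm - s)
    list(aperm(array(dz, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3)))
  })
}

# --- spatial ops -----------------------------------------------------------

sx_conv2d <- function(x, w, b, stride = 1L, pad = 0L) {
  xv <- x$value; wv <- w$value
  y <- cpp_conv2d_forward(xv, wv, as.vector(b$value), as.integer(stride),
                          as.integer(pad))
  sx_op(y, list(x, w, b), function(g) {
    gr <- cpp_conv2d_backward(xv, wv, g, as.integer(stride), as.integer(pad))
    list(gr$gx, gr$gw, gr$gb)
  })
}

sx_maxpool2 <- function(x) {
  d <- dim(x$value)
  f <- cpp_maxpool2_forward(x$value)
  sx_op(f$y, list(x), function(g) {
    if (is.null(dim(g))) dim(g) <- dim(f$y)
    list(cpp_maxpool2_backward(g, f$idx, as.integer(d)))
  })
}

sx_upsample2 <- function(x) {
  sx_op(cpp_upsample2_forward(x$value), list(x), function(g)
    list(cpp_upsample2_backward(g)))
}

sx_concat_channels <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  stopifnot(da[c(1, 2, 4)] == db[c(1, 2, 4)])
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a$value
  y[, , da[3] + seq_len(db[3]), ] <- b$value
  sx_op(y, list(a, b), function(g)
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE]))
}

# global average pool: (H,W,C,N) -> (N x C) matrix
sx_gap <- function(x) {
  d <- dim(x$value)
  y <- apply(x$value, c(4, 3), mean)
  if (is.null(dim(y))) y <- matrix(y, nrow = d[4], ncol = d[3])
  sx_op(y, list(x), function(g) {
    gx <- array(0, d)
    for (n in seq_len(d[4]))
      gx[, , , n] <- rep(g[n, ] / (d[1] * d[2]), each = d[1] * d[2])
    list(gx)
  })
}

# --- batch normalization ---------------------------------------------------

# `layer` is an environment with tensors gamma, beta and numeric buffers
# running_mean / running_var updated in place while training.  The heavy
# per-element work runs in single-pass C++ kernels on the native layout.
sx_batchnorm <- function(x, layer, training, momentum = 0.1, eps = 1e-5) {
  xv <- x$value
  gv <- as.vector(layer$gamma$value)
  bv <- as.vector(layer$beta$value)
  if (training) {
    st <- cpp_bn_stats(xv)
    mu <- st$mean
    va <- st$var
    layer$running_mean <- (1 - momentum) * layer$running_mean + momentum * mu
    layer$running_var <- (1 - momentum) * layer$running_var + momentum * va
  } else {
    mu <- layer$running_mean
    va <- layer$running_var
  }
  sd_ <- sqrt(va + eps)
  scale <- gv / sd_
  y <- cpp_bn_apply(xv, scale, bv - mu * scale)
  sx_op(y, list(x, layer$gamma, layer$beta), function(g) {
    if (is.null(dim(g))) dim(g) <- dim(xv)
    gs <- cpp_bn_grad_sums(g, xv, mu, sd_)
    gx <- if (training) {
      cpp_bn_backward_x(g, xv, mu, sd_, gv, gs$dgamma, gs$dbeta)
    } else {
      cpp_bn_apply(g, scale, numeric(length(scale)))
    }
    list(gx, gs$dgamma, gs$dbeta)
  })
}
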