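# Layer and module plumbing on top of the autodiff core.
# A "layer" is an environment (so batch-norm buffers can update in place);
# a "module" is an environment with $layers and a $forward(module, x, training).

# Evaluate `expr` with a temporarily fixed RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  args <- list(...)
  for (nm in names(args)) assign(nm, args[[nm]], envir = e)
  class(e) <- "sx_layer"
  e
}

# He-normal initialization for conv / linear weights.
nn_conv <- function(cin, cout, k, stride = 1L, pad = as.integer(k %/% 2)) {
  fan_in <- k * k * cin
  w <- array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / fan_in)),
             c(k, k, cin, cout))
  new_layer("conv", w = sx_param(w), b = sx_param(numeric(cout)),
            stride = as.integer(stride), pad = as.integer(pad))
}

nn_bn <- function(c) {
  new_layer("bn", gamma = sx_param(rep(1, c)), beta = sx_param(numeric(c)),
            running_mean = numeric(c), running_var = rep(1, c))
}

nn_linear <- function(cin, cout) {
  w <- matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout)
  new_layer("linear", w = sx_param(w), b = sx_param(numeric(cout)))
}

nn_resblock <- function(cin, cout, stride = 1L) {
  proj <- if (stride != 1L || cin != cout) nn_conv(cin, cout, 1L, stride, 0L) else NULL
  new_layer("resblock",
            conv1 = nn_conv(cin, cout, 3L, stride), bn1 = nn_bn(cout),
            conv2 = nn_conv(cout, cout, 3L), bn2 = nn_bn(cout),
            proj = proj, bnp = if (!is.null(proj)) nn_bn(cout) else NULL)
}

layer_forward <- function(layer, x, training) {
  switch(layer$type,
    conv = sx_conv2d(x, layer$w, layer$b, layer$stride, layer$pad),
    bn = sx_batchnorm(x, layer, training),
    relu = sx_relu(x),
    maxpool = sx_maxpool2(x),
    upsample = sx_upsample2(x),
    gap = sx_gap(x),
    linear = sx_bias_rows(sx_matmul(x, layer$w), layer$b),
    resblock = res_forward(layer, x, training),
    stop("unknown layer type: ", layer$type)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

res_forward <- function(layer, x, training) {
  h <- sx_conv2d(x, layer$conv1$w, layer$conv1$b, layer$conv1$stride, layer$conv1$pad)
  h <- sx_relu(sx_batchnorm(h, layer$bn1, training))
  h <- sx_conv2d(h, layer$conv2$w, layer$conv2$b, layer$conv2$stride, layer$conv2$pad)
  h <- sx_batchnorm(h, layer$bn2, training)
  skip <- if (is.null(layer$proj)) x else {
    s <- sx_conv2d(x, layer$proj$w, layer$proj$b, layer$proj$stride, layer$proj$pad)
    sx_batchnorm(s, layer$bnp, training)
  }
  sx_relu(sx_add(h, skip))
}

seq_forward <- function(layers, x, training) {
  for (layer in layers) {
    x <- if (layer$type == "resblock") res_forward(layer, x, training)
         else layer_forward(layer, x, training)
  }
  x
}

# Collect all trainable tensors of a layer / module, recursively.
collect_params <- function(obj) {
  out <- list()
  grab <- function(e) {
    for (nm in ls(e, sorted = TRUE)) {
      v <- get(nm, envir = e)
      if (inherits(v, "sx_tensor") && isTRUE(v$requires_grad)) out[[length(out) + 1L]] <<- v
      else if (inherits(v, "sx_layer")) grab(v)
      else if (is.list(v)) for (el in v) if (inherits(el, "sx_layer")) grab(el)
    }
  }
  if (inherits(obj, "sx_layer") || is.environment(obj)) grab(obj)
  else for (el in obj) if (inherits(el, "sx_layer")) grab(el) else if (is.environment(el)) grab(el)
  out
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p$value) %||% length(p$value))),
       v = lapply(params, function(p) array(0, dim = dim(p$value) %||% length(p$value))),
       t = 0L)
}

adam_step <- function(state, params, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * p$value
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mhat <- state$m[[i]] / bc1
    vhat <- state$v[[i]] / bc2
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

# --- backbone presets ------------------------------------------------------

# Sequential spec entries:
#   list("conv", cin, cout, k, stride, pad) / list("bn", c) / list("relu") /
#   list("maxpool") / list("gap") / list("linear", cin, cout) /
#   list("resblock", cin, cout, stride)
build_sequential <- function(spec) {
  lapply(spec, function(s) {
    switch(s[[1]],
      conv = nn_conv(s[[2]], s[[3]], s[[4]],
                     if (length(s) >= 5) s[[5]] else 1L,
                     if (length(s) >= 6) s[[6]] else as.integer(s[[4]] %/% 2)),
      bn = nn_bn(s[[2]]),
      relu = new_layer("relu"),
      maxpool = new_layer("maxpool"),
      upsample = new_layer("upsample"),
      gap = new_layer("gap"),
      linear = nn_linear(s[[2]], s[[3]]),
      resblock = nn_resblock(s[[2]], s[[3]], if (length(s) >= 4) s[[4]] else 1L),
      stop("unknown spec entry: ", s[[1]])
    )
  })
}

cbr <- function(cin, cout) list(list("conv", cin, cout, 3L), list("bn", cout), list("relu"))

# Image-classification backbones mapping (H,W,cin,N) -> (N x out_dim) logits.
# "small" is the desk-scale default; "vgg16-bn" and "resnet18" follow the
# standard configurations with a global-average-pool head, first layer widened
# to `cin` input channels, trained from scratch.
backbone_spec <- function(name, cin, out_dim, width = 8L) {
  switch(name,
    small = c(cbr(cin, width), list(list("maxpool")),
              cbr(width, 2L * width), list(list("maxpool")),
              cbr(2L * width, 4L * width), list(list("maxpool")),
              list(list("gap"), list("linear", 4L * width, out_dim))),
    `vgg16-bn` = {
      cfg <- c(64, 64, NA, 128, 128, NA, 256, 256, 256, NA,
               512, 512, 512, NA, 512, 512, 512, NA)
      spec <- list()
      prev <- cin
      for (v in cfg) {
        if (is.na(v)) spec <- c(spec, list(list("maxpool")))
        else { spec <- c(spec, cbr(prev, v)); prev <- v }
      }
      c(spec, list(list("gap"), list("linear", 512L, out_dim)))
    },
    resnet18 = {
      spec <- list(list("conv", cin, 64L, 7L, 2L, 3L), list("bn", 64L),
                   list("relu"), list("maxpool"),
                   list("resblock", 64L, 64L), list("resblock", 64L, 64L),
                   list("resblock", 64L, 128L, 2L), list("resblock", 128L, 128L),
                   list("resblock", 128L, 256L, 2L), list("resblock", 256L, 256L),
                   list("resblock", 256L, 512L, 2L), list("resblock", 512L, 512L),
                   list("gap"), list("linear", 512L, out_dim))
      spec
    },
    stop("unknown backbone: ", name)
  )
}

new_backbone <- function(name, cin, out_dim, width = 8L, rng_seed = 1L) {
  layers <- with_seed(rng_seed, build_sequential(backbone_spec(name, cin, out_dim, width)))
  m <- new.env(parent = emptyenv())
  m$name <- name
  m$cin <- cin
  m$out_dim <- out_dim
  m$layers <- layers
  class(m) <- "sx_module"
  m
}

backbone_forward <- function(module, x, training = FALSE) {
  seq_forward(module$layers, x, training)
}
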