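# Stage 3 forward contracts: the superpixel-generation network (per-pixel
# soft associations over N_S global superpixel candidates) and the
# superpixel-clustering network (per-image scores over the N_S superpixels).
#
# The generator is an encoder-decoder fully convolutional network with skip
# connections whose final 1x1 convolution emits N_S channels at full input
# resolution; a per-pixel softmax across those channels yields the
# association map Q.  The clusterer consumes the concatenation of the image
# and Q (4 + N_S channels) through an image-classification backbone
# (reference preset ResNet-18) and a softmax over its N_S logits yields the
# superpixel scores R.

#' Create a superpixel-generation network
#'
#' @param n_superpixels maximum number of superpixels N_S (default 64)
#' @param width base channel width of the encoder
#' @param rng_seed initialization seed
#' @return an object of class `superpixel_generator`
#' @export
new_superpixel_generator <- function(n_superpixels = 64L, width = 16L,
                                     rng_seed = 1L) {
  F1 <- as.integer(width); F2 <- 2L * F1; F4 <- 4L * F1
  g <- new.env(parent = emptyenv())
  g$n_superpixels <- as.integer(n_superpixels)
  g$width <- F1
  with_seed(rng_seed, {
    g$e1 <- nn_conv(4L, F1, 3L); g$bn1 <- nn_bn(F1)
    g$e2 <- nn_conv(F1, F2, 3L); g$bn2 <- nn_bn(F2)
    g$mid <- nn_conv(F2, F4, 3L); g$bnm <- nn_bn(F4)
    g$d2 <- nn_conv(F4 + F2, F2, 3L); g$bnd2 <- nn_bn(F2)
    g$d1 <- nn_conv(F2 + F1, F1, 3L); g$bnd1 <- nn_bn(F1)
    g$head <- nn_conv(F1, g$n_superpixels, 1L, 1L, 0L)
  })
  class(g) <- c("superpixel_generator", "sx_module")
  g
}

# tensor-level forward; returns the softmaxed association tensor (H,W,NS,N)
generator_forward_t <- function(gen, xt, training = FALSE) {
  d <- dim(xt$value)
  if (d[1] %% 4L != 0L || d[2] %% 4L != 0L)
    stop("generator input height and width must be divisible by 4 ",
         "(two 2x downsampling stages); got ", d[1], "x", d[2])
  a1 <- sx_relu(sx_batchnorm(sx_conv2d(xt, gen$e1$w, gen$e1$b, 1L, 1L),
                             gen$bn1, training))
  p1 <- sx_maxpool2(a1)
  a2 <- sx_relu(sx_batchnorm(sx_conv2d(p1, gen$e2$w, gen$e2$b, 1L, 1L),
                             gen$bn2, training))
  p2 <- sx_maxpool2(a2)
  am <- sx_relu(sx_batchnorm(sx_conv2d(p2, gen$mid$w, gen$mid$b, 1L, 1L),
                             gen$bnm, training))
  c2 <- sx_concat_channels(sx_upsample2(am), a2)
  b2 <- sx_relu(sx_batchnorm(sx_conv2d(c2, gen$d2$w, gen$d2$b, 1L, 1L),
                             gen$bnd2, training))
  c1 <- sx_concat_channels(sx_upsample2(b2), a1)
  b1 <- sx_relu(sx_batchnorm(sx_conv2d(c1, gen$d1$w, gen$d1$b, 1L, 1L),
                             gen$bnd1, training))
  z <- sx_conv2d(b1, gen$head$w, gen$head$b, 1L, 0L)
  sx_softmax_channels(z)
}

#' Soft superpixel associations for slices
#'
#' Runs the generator in eval mode.  For every pixel the N_S association
#' values are a probability simplex (softmax across channels), and the
#' output resolution equals the input resolution exactly.
#'
#' @param gen a [new_superpixel_generator()]
#' @param x an (H, W, 4) slice array or an (H, W, 4, N) batch
#' @return an (H, W, N_S) association array for a single slice, or
#'   (H, W, N_S, N) for a batch
#' @export
generator_forward <- function(gen, x) {
  single <- length(dim(x)) == 3L
  if (single) x <- array(x, c(dim(x), 1L))
  q <- sx_no_grad(generator_forward_t(gen, sx_const(x), training = FALSE))$value
  if (single) q[, , , 1] else q
}

#' Create a superpixel-clustering network
#'
#' @param n_superpixels number of superpixels N_S; the network consumes
#'   4 + N_S input channels and emits N_S logits
#' @param backbone `"resnet18"` (reference) or `"small"` (desk-scale)
#' @param width channel width of the `"small"` backbone
#' @param rng_seed initialization seed
#' @return an object of class `superpixel_clusterer`
#' @export
new_superpixel_clusterer <- function(n_superpixels = 64L,
                                     backbone = "resnet18", width = 8L,
                                     rng_seed = 2L) {
  m <- new_backbone(backbone, 4L + as.integer(n_superpixels),
                    as.integer(n_superpixels), width, rng_seed)
  m$n_superpixels <- as.integer(n_superpixels)
  class(m) <- c("superpixel_clusterer", class(m))
  m
}

# tensor-level forward from a pre-concatenated (H,W,4+NS,N) input
clusterer_forward_t <- function(clu, xcat, training = FALSE) {
  sx_softmax_rows(backbone_forward(clu, xcat, training))
}

#' Superpixel tumor scores for slices
#'
#' Concatenates the image with its association map and runs the clustering
#' backbone in eval mode; the N_S outputs are softmax-normalized so each
#' image's scores sum to 1.
#'
#' @param clu a [new_superpixel_clusterer()]
#' @param x an (H, W, 4) slice or (H, W, 4, N) batch
#' @param q the matching (H, W, N_S) or (H, W, N_S, N) association array
#' @return a length-N_S score vector (single slice) or an (N, N_S) matrix
#' @export
cluster_forward <- function(clu, x, q) {
  single <- length(dim(x)) == 3L
  if (single) {
    x <- array(x, c(dim(x), 1L))
    q <- array(q, c(dim(q), 1L))
  }
  if (dim(q)[3] != clu$n_superpixels)
    stop("association map has ", dim(q)[3], " superpixel channels but the ",
         "clusterer head expects ", clu$n_superpixels)
  xcat <- sx_concat_channels(sx_const(x), sx_const(q))
  r <- sx_no_grad(clusterer_forward_t(clu, xcat, training = FALSE))$value
  if (single) as.vector(r) else r
}

#' Number of effective superpixels in an association map
#'
#' A superpixel is effective if it is the argmax association of at least one
#' pixel; argmax ties resolve to the lowest superpixel index.  The result is
#' always in \[1, N_S\].
#'
#' @param q an (H, W, N_S) association array
#' @return integer count
#' @export
count_effective_superpixels <- function(q) {
  d <- dim(q)
  m <- matrix(q, d[1] * d[2], d[3])
  length(unique(max.col(m, ties.method = "first")))
}

#' Hard superpixel label map (argmax of the associations)
#' @param q an (H, W, N_S) association array
#' @return an (H, W) integer matrix of superpixel labels in 1..N_S
#' @export
superpixel_labels <- function(q) {
  d <- dim(q)
  matrix(max.col(matrix(q, d[1] * d[2], d[3]), ties.method = "first"),
         d[1], d[2])
}
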