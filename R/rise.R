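# Stage 2: randomized input-sampling (RISE) saliency and localization seeds.
#
# A fixed set of K random soft masks perturbs each image multiplicatively
# (occlusion toward 0, identically on all four channels); the classifier's
# probability on each masked image weights that mask's contribution to a
# per-pixel saliency heatmap.  The top 20% of heatmap values become positive
# seeds and the bottom 20% negative seeds; images the classifier calls
# healthy have their seeds replaced by all-negative maps.

#' Generate the shared RISE mask set
#'
#' Each mask starts as an s x s Bernoulli(keep_prob) cell grid, is bilinearly
#' upsampled to (H + cell_h) x (W + cell_w), randomly shifted by up to one
#' cell, and cropped to H x W - the canonical RISE construction.  One mask
#' set is generated once and reused across all images.
#'
#' @param image_shape (H, W) of the images to explain
#' @param K number of masks (reference value 4000)
#' @param cell_grid side length s of the coarse cell grid (default 8)
#' @param keep_prob Bernoulli keep probability (default 0.5), in (0, 1)
#' @param rng_seed seed; the same seed reproduces the identical mask set
#' @return an object of class `rise_masks` holding an (H, W, K) array of
#'   soft masks in \[0, 1\]
#' @export
generate_masks <- function(image_shape, K = 4000L, cell_grid = 8L,
                           keep_prob = 0.5, rng_seed = 0L) {
  if (K < 1L) stop("K must be positive")
  if (keep_prob <= 0 || keep_prob >= 1)
    stop("keep_prob must be strictly inside (0, 1); 0 or 1 masks carry no information")
  H <- as.integer(image_shape[1]); W <- as.integer(image_shape[2])
  s <- as.integer(cell_grid)
  ch <- ceiling(H / s); cw <- ceiling(W / s)
  masks <- array(0, c(H, W, K))
  with_seed(rng_seed, {
    chunk <- 256L
    for (s0 in seq(1L, K, by = chunk)) {
      idx <- s0:min(s0 + chunk - 1L, K)
      B <- length(idx)
      grid <- array(stats::rbinom(s * s * B, 1L, keep_prob), c(s, s, 1L, B))
      up <- cpp_bilinear_resize(grid, H + ch, W + cw)
      for (j in seq_len(B)) {
        oy <- sample.int(ch, 1L) - 1L
        ox <- sample.int(cw, 1L) - 1L
        masks[, , idx[j]] <- up[oy + seq_len(H), ox + seq_len(W), 1L, j]
      }
    }
  })
  structure(list(masks = masks, K = as.integer(K), cell_grid = s,
                 keep_prob = keep_prob, rng_seed = as.integer(rng_seed)),
            class = "rise_masks")
}

#' @export
print.rise_masks <- function(x, ...) {
  d <- dim(x$masks)
  cat(sprintf("<rise_masks> K=%d masks of %dx%d (cell grid %d, keep_prob %g)\n",
              x$K, d[1], d[2], x$cell_grid, x$keep_prob))
  invisible(x)
}

#' RISE saliency heatmap for one slice
#'
#' Computes `H(p) = (1 / (K * keep_prob)) * sum_i score_i * mask_i(p)` where
#' `score_i` is the classifier probability on the slice with mask i applied
#' multiplicatively to all four channels.  Deterministic given the model and
#' mask set.
#'
#' @param model a trained [train_classifier()] model (or any function taking
#'   an (H, W, 4, B) array and returning B probabilities)
#' @param slice an (H, W, 4) array
#' @param masks a [generate_masks()] mask set of matching spatial shape
#' @param batch number of masked copies evaluated per forward pass
#' @return an (H, W) saliency matrix
#' @export
rise_heatmap <- function(model, slice, masks, batch = 128L) {
  stopifnot(inherits(masks, "rise_masks"))
  d <- dim(slice)
  dm <- dim(masks$masks)
  if (!identical(as.integer(d[1:2]), as.integer(dm[1:2])))
    stop("slice and masks must share spatial shape")
  score_fn <- if (inherits(model, "tumor_classifier")) {
    function(x) classifier_probs(model, x, batch = dim(x)[4])
  } else if (is.function(model)) model
  else stop("model must be a tumor_classifier or a scoring function")
  K <- masks$K
  scores <- numeric(K)
  for (s0 in seq(1L, K, by = batch)) {
    idx <- s0:min(s0 + batch - 1L, K)
    B <- length(idx)
    mb <- masks$masks[, , idx, drop = FALSE]
    xm <- array(0, c(d[1], d[2], 4L, B))
    for (c in 1:4) xm[, , c, ] <- as.vector(slice[, , c]) * mb  # recycled over masks
    sc <- score_fn(xm)
    if (any(!is.finite(sc)))
      stop("model returned non-finite scores on masked inputs")
    scores[idx] <- sc
  }
  M <- matrix(masks$masks, d[1] * d[2], K)
  heat <- as.vector(M %*% scores) / (K * masks$keep_prob)
  matrix(heat, d[1], d[2])
}

#' Construct a seed map
#' @param positive,negative binary (H, W) matrices; must be disjoint
#' @return an object of class `seed_map`
#' @export
seed_map <- function(positive, negative) {
  stopifnot(identical(dim(positive), dim(negative)))
  positive <- (positive != 0) * 1
  negative <- (negative != 0) * 1
  if (any(positive * negative != 0))
    stop("positive and negative seeds must be disjoint")
  structure(list(positive = positive, negative = negative), class = "seed_map")
}

#' @export
print.seed_map <- function(x, ...) {
  P <- length(x$positive)
  cat(sprintf("<seed_map> %dx%d: %d positive, %d negative, %d unseeded\n",
              nrow(x$positive), ncol(x$positive), sum(x$positive),
              sum(x$negative), P - sum(x$positive) - sum(x$negative)))
  invisible(x)
}

#' Convert a saliency heatmap to localization seeds
#'
#' The `round(quantile * H * W)` pixels with the highest values become
#' positive seeds and the same count with the lowest values negative seeds;
#' the rest stays unseeded.  Ties are broken by stable raster order
#' (column-major), so the result is deterministic for any heatmap.
#'
#' @param heatmap an (H, W) matrix of finite values
#' @param quantile seeded fraction per class (default 0.2)
#' @return a [seed_map()]
#' @export
seeds_from_heatmap <- function(heatmap, quantile = 0.2) {
  if (!all(is.finite(heatmap))) stop("heatmap must be finite")
  P <- length(heatmap)
  if (P < 10L) stop("heatmap too small for quantile seeds (need >= 10 pixels)")
  n <- round(quantile * P)
  if (2L * n > P) stop("quantile too large: seed classes would overlap")
  ord <- order(as.vector(heatmap))  # ascending, stable in raster order
  neg <- ord[seq_len(n)]
  pos <- ord[(P - n + 1L):P]
  pmat <- matrix(0, nrow(heatmap), ncol(heatmap))
  nmat <- pmat
  pmat[pos] <- 1
  nmat[neg] <- 1
  seed_map(pmat, nmat)
}

#' Replace seeds of predicted-healthy images
#'
#' If the classifier predicts no tumor, the seed map is replaced by one with
#' no positive seeds and every pixel negative; otherwise it is returned
#' unchanged.  Idempotent.
#'
#' @param seeds a [seed_map()]
#' @param predicted_label the classifier's 0/1 decision for the image
#' @return a [seed_map()]
#' @export
apply_healthy_override <- function(seeds, predicted_label) {
  stopifnot(predicted_label %in% c(0L, 1L))
  if (predicted_label == 0L) {
    z <- seeds$positive * 0
    seed_map(z, z + 1)
  } else seeds
}

#' Generate seeds for every slice of a dataset
#'
#' Runs [rise_heatmap()] and [seeds_from_heatmap()] per slice, then applies
#' the healthy override using the classifier's own prediction (not the true
#' label, matching what is available at inference time).
#'
#' @param model a trained [train_classifier()] model
#' @param ds a [slice_dataset()]
#' @param masks a [generate_masks()] mask set
#' @param quantile seeded fraction per class
#' @param threshold classifier decision threshold for the override
#' @return list with `seeds` (list of [seed_map()]), `heatmaps` (H, W, N
#'   array), and `predicted` (0/1 vector)
#' @export
make_seeds <- function(model, ds, masks, quantile = 0.2, threshold = 0.5) {
  n <- length(ds)
  d <- dim(ds$pixels)
  predicted <- as.integer(classifier_probs(model, ds$pixels) >= threshold)
  heatmaps <- array(0, c(d[1], d[2], n))
  seeds <- vector("list", n)
  for (i in seq_len(n)) {
    h <- rise_heatmap(model, ds$pixels[, , , i], masks)
    heatmaps[, , i] <- h
    seeds[[i]] <- apply_healthy_override(seeds_from_heatmap(h, quantile),
                                         predicted[i])
  }
  list(seeds = seeds, heatmaps = heatmaps, predicted = predicted)
}
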