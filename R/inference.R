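# Soft clustering of superpixels into tumor heatmaps, validation-cohort
# threshold selection, and final binary segmentations with the
# healthy-image gate.

#' Soft-clustered tumor heatmap
#'
#' `H+(p) = sum_s q[p, s] * r[s]` - a convex combination of the simplex
#' weights, so values lie in \[0, 1\] automatically, and
#' `mean(H+) = sum_s r[s] * mean(q[s])` exactly.
#'
#' @param q an (H, W, N_S) association array
#' @param r a length-N_S superpixel score vector
#' @return an (H, W) tumor-probability matrix
#' @export
soft_cluster_heatmap <- function(q, r) {
  d <- dim(q)
  stopifnot(length(r) == d[3])
  matrix(matrix(q, d[1] * d[2], d[3]) %*% as.vector(r), d[1], d[2])
}

#' Select the decision threshold on the validation cohort
#'
#' Evaluates the mean per-image Dice of `heatmap >= t` against the reference
#' masks for t on a grid (default 0.1, 0.2, ..., 0.9) and returns the
#' maximizer; ties break toward the larger threshold (less-segmented
#' output).  This follows the reference protocol, which uses validation
#' reference masks for this single scalar - a weak-supervision leak kept for
#' fidelity; set `unsupervised = TRUE` to skip it and use a fixed 0.5.
#'
#' @param heatmaps an (H, W, N) array of validation tumor heatmaps
#' @param reference_masks the matching (H, W, N) binary masks
#' @param grid_step spacing of the threshold grid (default 0.1)
#' @param unsupervised if TRUE, return 0.5 without touching the masks
#' @return the selected threshold
#' @export
select_threshold <- function(heatmaps, reference_masks, grid_step = 0.1,
                             unsupervised = FALSE) {
  if (unsupervised) return(0.5)
  d <- dim(heatmaps)
  if (length(d) != 3L || d[3] < 1L) stop("empty validation set")
  stopifnot(identical(dim(reference_masks), d))
  grid <- seq(grid_step, 1 - grid_step + 1e-9, by = grid_step)
  mean_dice <- vapply(grid, function(t) {
    mean(vapply(seq_len(d[3]), function(i)
      dice((heatmaps[, , i] >= t) * 1, reference_masks[, , i]), 0))
  }, 0)
  max(grid[mean_dice >= max(mean_dice) - 1e-12])
}

#' Segment one slice
#'
#' If the classifier predicts healthy, the mask is empty regardless of the
#' heatmap; otherwise the mask is `H+ >= threshold` (ties segmented).
#'
#' @param pixels an (H, W, 4) slice array
#' @param gen,clu trained superpixel generator and clusterer
#' @param classifier a trained [train_classifier()] model, or NULL to skip
#'   the gate
#' @param threshold heatmap decision threshold
#' @param classifier_threshold probability cutoff of the gate (default 0.5)
#' @return an object of class `segmentation`: list with `mask` (H, W binary),
#'   `heatmap`, `threshold_used`, `classifier_gate`
#' @export
segment_slice <- function(pixels, gen, clu, classifier = NULL,
                          threshold = 0.5, classifier_threshold = 0.5) {
  q <- generator_forward(gen, pixels)
  r <- cluster_forward(clu, pixels, q)
  h <- soft_cluster_heatmap(q, r)
  gate <- if (is.null(classifier)) 1L
          else as.integer(predict_tumor_probability(classifier, pixels) >=
                            classifier_threshold)
  mask <- if (gate == 0L) h * 0 else (h >= threshold) * 1
  structure(list(mask = mask, heatmap = h, threshold_used = threshold,
                 classifier_gate = gate),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %dx%d, %d pixels segmented (threshold %g, gate %d)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$threshold_used,
              x$classifier_gate))
  invisible(x)
}

#' Segment every slice of a dataset
#'
#' @param ds a [slice_dataset()]
#' @inheritParams segment_slice
#' @return list with `masks` and `heatmaps` (H, W, N arrays), `gate`
#'   (0/1 vector), and `threshold_used`
#' @export
segment_dataset <- function(ds, gen, clu, classifier = NULL, threshold = 0.5,
                            classifier_threshold = 0.5) {
  d <- dim(ds$pixels)
  n <- d[4]
  q <- generator_forward(gen, ds$pixels)
  r <- cluster_forward(clu, ds$pixels, q)
  gate <- if (is.null(classifier)) rep(1L, n)
          else as.integer(classifier_probs(classifier, ds$pixels) >=
                            classifier_threshold)
  masks <- array(0, c(d[1], d[2], n))
  heatmaps <- array(0, c(d[1], d[2], n))
  for (i in seq_len(n)) {
    h <- soft_cluster_heatmap(q[, , , i], r[i, ])
    heatmaps[, , i] <- h
    if (gate[i] == 1L) masks[, , i] <- (h >= threshold) * 1
  }
  list(masks = masks, heatmaps = heatmaps, gate = gate,
       threshold_used = threshold)
}
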