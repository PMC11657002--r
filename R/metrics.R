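# Evaluation metrics: smoothed Dice, undersegmented Dice, and the 95th
# percentile Hausdorff distance with the empty-mask conventions.

check_masks <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
}

#' Dice coefficient with smoothing
#'
#' `(2 |A intersect B| + smooth) / (|A| + |B| + smooth)`.  With the default
#' smoothing of 1, two empty masks score 1.  Symmetric in its arguments.
#'
#' @param a,b binary masks of identical shape
#' @param smooth smoothing factor (default 1)
#' @return scalar in \[0, 1\]
#' @export
dice <- function(a, b, smooth = 1) {
  check_masks(a, b)
  a <- a != 0; b <- b != 0
  (2 * sum(a & b) + smooth) / (sum(a) + sum(b) + smooth)
}

#' Undersegmented Dice coefficient
#'
#' `0` when A is empty but B is not; otherwise
#' `(|A intersect B| + smooth) / (|A| + smooth)` - the fraction of A lying
#' inside B, i.e. how well A undersegments B.  Equals 1 whenever A is a
#' subset of B (including both empty).  Not symmetric: A is the seed or
#' proposed segmentation, B the ground truth.
#'
#' @inheritParams dice
#' @return scalar in \[0, 1\]
#' @export
u_dice <- function(a, b, smooth = 1) {
  check_masks(a, b)
  a <- a != 0; b <- b != 0
  if (sum(a) == 0 && sum(b) > 0) return(0)
  (sum(a & b) + smooth) / (sum(a) + smooth)
}

# boundary pixels: mask pixels with at least one non-mask 4-neighbor
# (image border counts as outside)
boundary_coords <- function(m) {
  m <- m != 0
  H <- nrow(m); W <- ncol(m)
  up <- rbind(FALSE, m[-H, , drop = FALSE])
  down <- rbind(m[-1, , drop = FALSE], FALSE)
  left <- cbind(FALSE, m[, -W, drop = FALSE])
  right <- cbind(m[, -1, drop = FALSE], FALSE)
  b <- m & !(up & down & left & right)
  which(b, arr.ind = TRUE)
}

#' 95th percentile Hausdorff distance
#'
#' Euclidean distances (pixel units) from each boundary pixel of A to its
#' nearest boundary pixel of B; the 95th percentile of those ordered
#' distances (linear-interpolation percentile) is returned.  By the adopted
#' convention the result is 0 when either mask is empty.  The default is the
#' directed A-to-B distance; `symmetric = TRUE` returns the maximum of the
#' two directed HD95 values, as most BraTS tooling reports.
#'
#' @inheritParams dice
#' @param symmetric compute the symmetric variant (default FALSE)
#' @return scalar distance >= 0
#' @export
hd95 <- function(a, b, symmetric = FALSE) {
  check_masks(a, b)
  if (sum(a != 0) == 0 || sum(b != 0) == 0) return(0)
  if (symmetric) return(max(hd95(a, b), hd95(b, a)))
  ca <- boundary_coords(a)
  cb <- boundary_coords(b)
  d2 <- outer(ca[, 1], cb[, 1], "-")^2 + outer(ca[, 2], cb[, 2], "-")^2
  dmin <- sqrt(apply(d2, 1, min))
  as.numeric(stats::quantile(dmin, 0.95, names = FALSE, type = 7))
}

#' Evaluate a cohort of segmentations
#'
#' Per-image Dice, HD95, and U-Dice between predicted and reference masks,
#' plus cohort means stratified by classifier correctness.
#'
#' @param masks predicted (H, W, N) binary mask array
#' @param references matching (H, W, N) reference mask array
#' @param classifier_correct optional logical vector: was the image-level
#'   classification correct for each image
#' @param id optional identifier vector
#' @return an object of class `cohort_eval`: list with `per_image` (tibble:
#'   id, dice, hd95, u_dice, classifier_correct) and `summary` (tibble of
#'   stratified means)
#' @export
evaluate_cohort <- function(masks, references, classifier_correct = NULL,
                            id = NULL) {
  dm <- dim(masks)
  if (!identical(dm, dim(references)))
    stop("masks and references differ in shape or count")
  n <- dm[3]
  if (is.null(id)) id <- seq_len(n)
  if (is.null(classifier_correct)) classifier_correct <- rep(NA, n)
  stopifnot(length(id) == n, length(classifier_correct) == n)
  per <- tibble::tibble(
    id = id,
    dice = vapply(seq_len(n), function(i) dice(masks[, , i], references[, , i]), 0),
    hd95 = vapply(seq_len(n), function(i) hd95(masks[, , i], references[, , i]), 0),
    u_dice = vapply(seq_len(n), function(i) u_dice(masks[, , i], references[, , i]), 0),
    classifier_correct = classifier_correct
  )
  strata <- list(all = rep(TRUE, n),
                 correct = classifier_correct %in% TRUE,
                 incorrect = classifier_correct %in% FALSE)
  summ <- do.call(rbind, lapply(names(strata), function(s) {
    k <- strata[[s]]
    tibble::tibble(stratum = s, n = sum(k),
                   mean_dice = if (any(k)) mean(per$dice[k]) else NA_real_,
                   mean_hd95 = if (any(k)) mean(per$hd95[k]) else NA_real_,
                   mean_u_dice = if (any(k)) mean(per$u_dice[k]) else NA_real_)
  }))
  structure(list(per_image = per, summary = summ), class = "cohort_eval")
}

#' @export
print.cohort_eval <- function(x, ...) {
  cat("<cohort_eval>\n")
  print(x$summary)
  invisible(x)
}
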