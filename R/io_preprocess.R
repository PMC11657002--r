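# BraTS-style preprocessing: foreground crop, percentile clipping with
# min-max scaling, axial slicing with end-slice removal, 128x128 patching,
# and the patient-level cohort split.

#' Read a multimodal volume from per-modality NIfTI files
#'
#' @param paths named character vector/list with elements `t1`, `t1ce`, `t2`,
#'   `flair` (channel order of the returned volume) and optionally `seg`,
#'   each a `.nii`/`.nii.gz` path.
#' @return a [multimodal_volume()]
#' @export
read_multimodal_volume <- function(paths) {
  paths <- as.list(paths)
  missing_mod <- setdiff(MODALITIES, names(paths))
  if (length(missing_mod))
    stop("missing modalities: ", paste(missing_mod, collapse = ", "))
  imgs <- lapply(MODALITIES, function(m) {
    v <- as.array(RNifti::readNifti(paths[[m]]))
    if (length(dim(v)) != 3L) stop("modality ", m, " is not a 3D volume")
    v
  })
  d <- dim(imgs[[1]])
  for (i in 2:4) if (!identical(dim(imgs[[i]]), d))
    stop("modality volumes do not share one shape")
  channels <- array(0, c(d, 4L))
  for (i in 1:4) channels[, , , i] <- imgs[[i]]
  mask <- NULL
  if (!is.null(paths$seg)) {
    mask <- as.array(RNifti::readNifti(paths$seg))
    if (!identical(dim(mask), d)) stop("segmentation shape mismatch")
  }
  multimodal_volume(channels, mask)
}

#' Crop a volume to the brain foreground
#'
#' Restricts the volume to the tightest axis-aligned bounding box containing
#' every voxel that is nonzero in any modality; the reference mask is cropped
#' with the same box.
#'
#' @param volume a [multimodal_volume()]
#' @return the cropped `multimodal_volume`
#' @export
crop_to_foreground <- function(volume) {
  fg <- apply(volume$channels != 0, 1:3, any)
  if (!any(fg)) stop("no foreground: volume is all zero")
  rng <- lapply(1:3, function(ax) range(which(apply(fg, ax, any))))
  ch <- volume$channels[rng[[1]][1]:rng[[1]][2],
                        rng[[2]][1]:rng[[2]][2],
                        rng[[3]][1]:rng[[3]][2], , drop = FALSE]
  mk <- if (!is.null(volume$reference_mask))
    volume$reference_mask[rng[[1]][1]:rng[[1]][2],
                          rng[[2]][1]:rng[[2]][2],
                          rng[[3]][1]:rng[[3]][2], drop = FALSE]
  multimodal_volume(ch, mk)
}

#' Clip intensities to percentiles and min-max scale
#'
#' Per channel, the `lo_pct`/`hi_pct` percentiles are computed over nonzero
#' voxels only (linear-interpolation percentiles, per volume); nonzero voxels
#' are clipped to that range, and the whole channel is then min-max scaled to
#' \[0, 1\].  Zero background therefore stays 0 whenever the channel minimum
#' is 0.  A channel with fewer than two distinct nonzero values falls back to
#' mapping its nonzero voxels to 1, with a warning.
#'
#' @param volume a [multimodal_volume()] (normally already cropped)
#' @param lo_pct,hi_pct clipping percentiles (defaults 1 and 99)
#' @return the normalized `multimodal_volume`
#' @export
clip_and_normalize <- function(volume, lo_pct = 1, hi_pct = 99) {
  ch <- volume$channels
  for (c in 1:4) {
    v <- ch[, , , c]
    nz <- v[v != 0]
    if (length(unique(nz)) < 2L) {
      warning("channel ", c, " has < 2 distinct nonzero values; ",
              "mapping nonzero voxels to 1")
      v[v != 0] <- 1
      ch[, , , c] <- v
      next
    }
    q <- stats::quantile(nz, c(lo_pct, hi_pct) / 100, names = FALSE, type = 7)
    v[v != 0] <- pmin(pmax(v[v != 0], q[1]), q[2])
    mn <- min(v); mx <- max(v)
    ch[, , , c] <- if (mx > mn) (v - mn) / (mx - mn) else v * 0
  }
  multimodal_volume(ch, volume$reference_mask)
}

#' Split a volume into labeled axial slices
#'
#' The first and last `drop_slices` axial slices (third array axis) are
#' removed; each remaining slice receives label 1 if its reference-mask
#' cross-section is non-empty and 0 if it is empty (NA when the volume has
#' no reference mask).
#'
#' @param volume a [multimodal_volume()]
#' @param drop_slices number of slices removed from each end (default 30)
#' @param patient_id identifier recorded with every slice
#' @return a [slice_dataset()]
#' @export
volume_to_slices <- function(volume, drop_slices = 30L, patient_id = NA_character_) {
  d <- dim(volume$channels)
  D <- d[3]
  if (D <= 2L * drop_slices)
    stop("axial depth ", D, " too small: need more than ", 2L * drop_slices,
         " slices to drop ", drop_slices, " from each end")
  keep <- (drop_slices + 1L):(D - drop_slices)
  px <- aperm(volume$channels[, , keep, , drop = FALSE], c(1, 2, 4, 3))
  mk <- NULL
  label <- rep(NA_integer_, length(keep))
  if (!is.null(volume$reference_mask)) {
    mk <- volume$reference_mask[, , keep, drop = FALSE]
    label <- as.integer(apply(mk, 3, sum) > 0)
  }
  slice_dataset(px, label, mk, rep(patient_id, length(keep)), keep)
}

patch_window <- function(H, W, size, random) {
  if (random) {
    c(sample.int(H - size + 1L, 1L), sample.int(W - size + 1L, 1L))
  } else {
    c((H - size) %/% 2L + 1L, (W - size) %/% 2L + 1L)
  }
}

pad_to <- function(a, size) {
  d <- dim(a)
  if (d[1] >= size && d[2] >= size) return(a)
  H2 <- max(d[1], size); W2 <- max(d[2], size)
  out <- array(0, c(H2, W2, d[-(1:2)]))
  oh <- (H2 - d[1]) %/% 2L; ow <- (W2 - d[2]) %/% 2L
  idx <- c(list(oh + seq_len(d[1]), ow + seq_len(d[2])),
           lapply(d[-(1:2)], seq_len))
  do.call(`[<-`, c(list(out), idx, list(value = a)))
}

#' Crop every slice of a dataset to a fixed square patch
#'
#' Training uses a random window per slice (deterministic for a fixed seed);
#' validation/test use the fixed center window.  The identical window is
#' applied to all four channels and to the reference mask.  Slices smaller
#' than `size` are first zero-padded symmetrically.
#'
#' @param ds a [slice_dataset()]
#' @param size patch side length (default 128)
#' @param rng_seed RNG seed for the random windows
#' @param mode `"random"` (train-time augmentation) or `"center"`
#' @return a `slice_dataset` of `size` x `size` patches
#' @export
patch_slices <- function(ds, size = 128L, rng_seed = 0L,
                         mode = c("random", "center")) {
  mode <- match.arg(mode)
  n <- length(ds)
  padded_px <- pad_to(ds$pixels, size)
  padded_mk <- if (!is.null(ds$mask)) pad_to(ds$mask, size)
  if (dim(padded_px)[1] > dim(ds$pixels)[1] || dim(padded_px)[2] > dim(ds$pixels)[2])
    message("patch_slices: slices smaller than ", size, " were zero-padded")
  H <- dim(padded_px)[1]; W <- dim(padded_px)[2]
  out_px <- array(0, c(size, size, 4L, n))
  out_mk <- if (!is.null(padded_mk)) array(0, c(size, size, n))
  with_seed(rng_seed, {
    for (i in seq_len(n)) {
      w0 <- patch_window(H, W, size, mode == "random")
      rows <- w0[1]:(w0[1] + size - 1L); cols <- w0[2]:(w0[2] + size - 1L)
      out_px[, , , i] <- padded_px[rows, cols, , i]
      if (!is.null(out_mk)) out_mk[, , i] <- padded_mk[rows, cols, i]
    }
  })
  label <- ds$label
  if (!is.null(out_mk)) label <- as.integer(apply(out_mk, 3, sum) > 0)
  slice_dataset(out_px, label, out_mk, ds$patient_id, ds$slice_index)
}

#' Patient-level train/validation/test split
#'
#' Splits patient identifiers (never slices) into disjoint cohorts.  Sizes
#' are `floor(train)`, `round(val)`, and the remainder for test, which
#' reproduces the 295/37/37 split of 369 patients at (0.8, 0.1, 0.1).
#'
#' @param patients character vector of patient identifiers
#' @param fractions length-3 numeric summing to 1 (train, val, test)
#' @param rng_seed RNG seed for the shuffle
#' @return list with character vectors `train`, `val`, `test`
#' @export
split_cohorts <- function(patients, fractions = c(0.8, 0.1, 0.1), rng_seed = 0L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three numbers summing to 1")
  patients <- unique(as.character(patients))
  n <- length(patients)
  perm <- with_seed(rng_seed, sample(patients))
  n_train <- floor(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  if (n_train + n_val > n) n_val <- n - n_train
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[setdiff(seq_len(n), seq_len(n_train + n_val))]))
}
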