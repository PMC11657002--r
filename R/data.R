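# Containers for multimodal volumes and 2D slice datasets.
#
# A `multimodal_volume` holds the four co-registered MR modalities of one
# patient as a single (H, W, D, 4) array, channel order fixed as
# (T1, post-contrast T1, T2, T2-FLAIR), plus an optional aligned binary
# reference mask used for evaluation only.
#
# A `slice_dataset` holds N 2D multimodal slices as a (H, W, 4, N) array with
# per-slice binary labels, optional (H, W, N) reference masks, and identifier
# columns.  The third array axis of a volume is the axial depth.

MODALITIES <- c("t1", "t1ce", "t2", "flair")

#' Construct a multimodal MR volume
#'
#' @param channels numeric array of shape (H, W, D, 4), channel order
#'   T1, post-contrast T1, T2, T2-FLAIR; the third axis is axial depth.
#' @param reference_mask optional binary (H, W, D) array aligned with
#'   `channels` (evaluation only).
#' @return an object of class `multimodal_volume`
#' @export
multimodal_volume <- function(channels, reference_mask = NULL) {
  d <- dim(channels)
  if (length(d) != 4L || d[4] != 4L)
    stop("channels must be an (H, W, D, 4) array")
  if (!all(is.finite(channels))) stop("channel values must be finite")
  if (!is.null(reference_mask)) {
    if (!identical(dim(reference_mask), d[1:3]))
      stop("reference_mask must share the (H, W, D) shape of the channels")
    reference_mask <- (reference_mask != 0) * 1
  }
  structure(list(channels = channels, reference_mask = reference_mask),
            class = "multimodal_volume")
}

#' @export
print.multimodal_volume <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<multimodal_volume> %d x %d x %d voxels, 4 modalities (%s)\n",
              d[1], d[2], d[3], paste(MODALITIES, collapse = ", ")))
  cat(if (is.null(x$reference_mask)) "  no reference mask\n"
      else sprintf("  reference mask: %d voxels\n", sum(x$reference_mask)))
  invisible(x)
}

#' Construct a slice dataset
#'
#' @param pixels numeric array (H, W, 4, N) with values in \[0, 1\]
#' @param label integer vector of N binary tumor-presence labels
#' @param mask optional (H, W, N) binary reference-mask array
#' @param patient_id,slice_index identifier vectors of length N
#' @return an object of class `slice_dataset`
#' @export
slice_dataset <- function(pixels, label, mask = NULL,
                          patient_id = NULL, slice_index = NULL) {
  d <- dim(pixels)
  if (length(d) != 4L || d[3] != 4L)
    stop("pixels must be an (H, W, 4, N) array")
  n <- d[4]
  stopifnot(length(label) == n)
  if (!is.null(mask)) stopifnot(identical(dim(mask), c(d[1], d[2], n)))
  if (is.null(patient_id)) patient_id <- rep(NA_character_, n)
  if (is.null(slice_index)) slice_index <- seq_len(n)
  structure(list(pixels = pixels, label = as.integer(label), mask = mask,
                 patient_id = as.character(patient_id),
                 slice_index = as.integer(slice_index)),
            class = "slice_dataset")
}

#' @export
length.slice_dataset <- function(x) dim(x$pixels)[4]

#' @export
print.slice_dataset <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slice_dataset> %d slices of %d x %d x 4, %d labeled positive%s\n",
              d[4], d[1], d[2], sum(x$label == 1L),
              if (is.null(x$mask)) ", no reference masks" else ""))
  invisible(x)
}

#' Subset a slice dataset
#' @param ds a `slice_dataset`
#' @param idx integer or logical index vector
#' @return a `slice_dataset` with the selected slices
#' @export
ds_subset <- function(ds, idx) {
  slice_dataset(ds$pixels[, , , idx, drop = FALSE], ds$label[idx],
                if (!is.null(ds$mask)) ds$mask[, , idx, drop = FALSE],
                ds$patient_id[idx], ds$slice_index[idx])
}

#' Extract one slice as a list
#' @param ds a `slice_dataset`
#' @param i slice number
#' @return list with elements `pixels` (H, W, 4), `label`, `mask` (or NULL)
#' @export
get_slice <- function(ds, i) {
  list(pixels = ds$pixels[, , , i],
       label = ds$label[i],
       mask = if (!is.null(ds$mask)) ds$mask[, , i],
       patient_id = ds$patient_id[i],
       slice_index = ds$slice_index[i])
}

#' Manifest table of a slice dataset
#' @param x a `slice_dataset`
#' @param ... unused
#' @return a tibble with one row per slice
#' @exportS3Method tibble::as_tibble
as_tibble.slice_dataset <- function(x, ...) {
  tibble::tibble(patient_id = x$patient_id, slice_index = x$slice_index,
                 label = x$label,
                 mask_area = if (is.null(x$mask)) NA_integer_
                             else as.integer(apply(x$mask, 3, sum)))
}

#' Write a slice dataset to disk
#'
#' Stores the pixel (and mask) arrays in one serialized container
#' (`slices.rds`) next to a plain-text `manifest.csv` listing patient id,
#' slice index, and label per slice.
#'
#' @param ds a `slice_dataset`
#' @param dir output directory (created if missing)
#' @param cohort optional cohort name recorded in the manifest
#'   (e.g. "train")
#' @return `dir`, invisibly
#' @export
write_slice_dataset <- function(ds, dir, cohort = NA_character_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(ds, file.path(dir, "slices.rds"))
  manifest <- as_tibble.slice_dataset(ds)
  manifest$cohort <- cohort
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a slice dataset written by [write_slice_dataset()]
#' @param dir dataset directory
#' @return a `slice_dataset`
#' @export
read_slice_dataset <- function(dir) {
  readRDS(file.path(dir, "slices.rds"))
}
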