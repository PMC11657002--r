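# Multimodal lesion phantom generator.
#
# Each phantom slice is a smooth "brain" disk with correlated low-frequency
# texture across the four channels, optionally carrying one focal lesion
# built as a union of 1-3 overlapping ellipses that is brightened per channel
# (largest offset on the T2-FLAIR-like channel 4), plus Gaussian noise, on a
# fixed [0, 1] intensity scale.  The lesion support is kept as the
# reference mask, used only for evaluation; the training signal is the
# binary image-level label (mask non-empty).

#' Phantom dataset configuration
#'
#' @param n_images number of slices to generate
#' @param image_size (H, W) in pixels
#' @param lesion_prevalence fraction of slices carrying a lesion, in \[0, 1\];
#'   the generated count is `round(prevalence * n_images)`
#' @param lesion_radius_range ellipse semi-axis range in pixels; must be
#'   positive and below `min(H, W) / 2`
#' @param lesion_contrast additive intensity offset per channel (length 4);
#'   conventionally largest on channel 4 (FLAIR-like)
#' @param background_texture_scale smoothness of the background random field
#'   (pixels per texture cell)
#' @param noise_sd standard deviation of the additive Gaussian noise
#' @param rng_seed RNG seed; regeneration with the same config is
#'   bit-identical
#' @return an object of class `phantom_config`
#' @export
phantom_config <- function(n_images = 256L,
                           image_size = c(32L, 32L),
                           lesion_prevalence = 0.7,
                           lesion_radius_range = c(4, 8),
                           lesion_contrast = c(0.15, 0.25, 0.3, 0.45),
                           background_texture_scale = 8,
                           noise_sd = 0.05,
                           rng_seed = 1L) {
  if (lesion_prevalence < 0 || lesion_prevalence > 1)
    stop("lesion_prevalence must be in [0, 1]")
  if (any(lesion_radius_range <= 0) ||
      max(lesion_radius_range) >= min(image_size) / 2)
    stop("lesion_radius_range must be positive and below min(H, W) / 2")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  stopifnot(length(lesion_contrast) == 4L, n_images >= 1L)
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 lesion_prevalence = lesion_prevalence,
                 lesion_radius_range = lesion_radius_range,
                 lesion_contrast = lesion_contrast,
                 background_texture_scale = background_texture_scale,
                 noise_sd = noise_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_config")
}

# smooth random field in roughly [-1, 1]: coarse normal grid, bilinear upsample
smooth_field <- function(H, W, scale) {
  gh <- max(2L, ceiling(H / scale) + 1L)
  gw <- max(2L, ceiling(W / scale) + 1L)
  g <- array(stats::rnorm(gh * gw), c(gh, gw, 1L, 1L))
  cpp_bilinear_resize(g, H, W)[, , 1, 1]
}

ellipse_mask <- function(H, W, cy, cx, a, b, theta) {
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  u <- yy * cos(theta) + xx * sin(theta)
  v <- -yy * sin(theta) + xx * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate a phantom multimodal slice dataset
#'
#' @param config a [phantom_config()]
#' @param n_images,rng_seed optional overrides of the config fields (used to
#'   draw validation/test cohorts from the same condition)
#' @return a [slice_dataset()] with reference masks
#' @export
generate_phantom <- function(config, n_images = NULL, rng_seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  n <- as.integer(n_images %||% config$n_images)
  seed <- as.integer(rng_seed %||% config$rng_seed)
  H <- config$image_size[1]; W <- config$image_size[2]
  rr <- config$lesion_radius_range
  px <- array(0, c(H, W, 4L, n))
  mk <- array(0, c(H, W, n))
  with_seed(seed, {
    n_lesion <- round(config$lesion_prevalence * n)
    has_lesion <- seq_len(n) %in% sample.int(n, n_lesion)
    rmax <- ceiling(max(rr))
    for (i in seq_len(n)) {
      # brain disk with slightly jittered radius
      cy <- H / 2 + stats::runif(1, -1, 1)
      cx <- W / 2 + stats::runif(1, -1, 1)
      brad <- 0.46 * min(H, W) * stats::runif(1, 0.95, 1.05)
      brain <- ellipse_mask(H, W, cy, cx, brad, brad * stats::runif(1, 0.9, 1), 0)
      shared <- smooth_field(H, W, config$background_texture_scale)
      lesion <- matrix(FALSE, H, W)
      if (has_lesion[i]) {
        n_ell <- sample.int(3L, 1L)
        ecy <- stats::runif(1, rmax + 1, H - rmax)
        ecx <- stats::runif(1, rmax + 1, W - rmax)
        for (e in seq_len(n_ell)) {
          a <- stats::runif(1, rr[1], rr[2])
          b <- stats::runif(1, rr[1], rr[2])
          th <- stats::runif(1, 0, pi)
          oy <- if (e == 1) 0 else stats::runif(1, -0.5, 0.5) * a
          ox <- if (e == 1) 0 else stats::runif(1, -0.5, 0.5) * b
          lesion <- lesion | ellipse_mask(H, W, ecy + oy, ecx + ox, a, b, th)
        }
      }
      for (c in 1:4) {
        own <- smooth_field(H, W, config$background_texture_scale)
        field <- 0.7 * shared + 0.3 * own
        img <- (0.4 + 0.1 * field) * brain
        img <- img + config$lesion_contrast[c] * lesion
        img <- img + stats::rnorm(H * W, sd = config$noise_sd)
        # fixed intensity scale (clamped), as after volume-level
        # normalization: the background distribution must not depend on
        # lesion presence, or image-level labels leak into global intensity
        px[, , c, i] <- pmin(pmax(img, 0), 1)
      }
      mk[, , i] <- lesion * 1
    }
  })
  label <- as.integer(apply(mk, 3, sum) > 0)
  slice_dataset(px, label, mk,
                patient_id = sprintf("phantom-%04d", seq_len(n)),
                slice_index = seq_len(n))
}

#' Named phantom difficulty conditions
#'
#' Returns the fixed conditions used by the package's own desk-scale study:
#' `easy` (high lesion contrast, larger lesions), `hard` (low contrast,
#' small lesions, more noise), and `healthy_only` (prevalence 0).
#'
#' @return named list of [phantom_config()] objects
#' @export
phantom_difficulty_suite <- function() {
  list(
    easy = phantom_config(n_images = 256L, image_size = c(32L, 32L),
                          lesion_prevalence = 0.7,
                          lesion_radius_range = c(5, 9),
                          lesion_contrast = c(0.2, 0.3, 0.4, 0.6),
                          noise_sd = 0.05, rng_seed = 101L),
    hard = phantom_config(n_images = 256L, image_size = c(32L, 32L),
                          lesion_prevalence = 0.7,
                          lesion_radius_range = c(2, 4),
                          lesion_contrast = c(0.05, 0.08, 0.1, 0.15),
                          noise_sd = 0.08, rng_seed = 102L),
    healthy_only = phantom_config(n_images = 256L, image_size = c(32L, 32L),
                                  lesion_prevalence = 0,
                                  lesion_radius_range = c(4, 8),
                                  lesion_contrast = c(0.2, 0.3, 0.4, 0.6),
                                  noise_sd = 0.05, rng_seed = 103L)
  )
}
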