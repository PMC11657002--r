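# Training objective: superpixel compactness loss + seeding loss.
#
# L_spixel penalizes, for every pixel, the unsquared Euclidean distance
# between the pixel's intensity (position) and its reconstruction from the
# soft-association-weighted superpixel mean intensities (locations):
#   L_spixel = (1/N) sum_k sum_p ( ||f(p) - sum_s u_s q_sp||_2
#                                  + m ||p - sum_s l_s q_sp||_2 )
# The seeding loss drives the soft-clustered tumor heatmap H+ toward 1 on
# positive seeds and 0 on negative seeds:
#   L_seed = -(1/N) sum_k [ sum_{S+} log H+ + sum_{S-} log(1 - H+) ]
#            / (|S+| + |S-|)
# and the combined objective is L = L_spixel + alpha * L_seed.
#
# Conventions: sums over pixels, mean over the images of a batch; pixel
# coordinates are raw 0-based (row, col) indices; norms are unsquared
# Euclidean distances; logs are floored at `eps`.

#' Loss configuration
#'
#' @param m superpixel-size coefficient weighting the position term
#'   (reference value 3/160 at 128 x 128 resolution)
#' @param alpha weight of the seeding loss (reference value 50)
#' @param eps numerical floor inside the seed-loss logarithms
#' @return an object of class `loss_config`
#' @export
loss_config <- function(m = 3 / 160, alpha = 50, eps = 1e-7) {
  stopifnot(m > 0, alpha >= 0, eps > 0)
  structure(list(m = m, alpha = alpha, eps = eps), class = "loss_config")
}

# pixel-feature constants of one (H,W,4) slice: F (P x 4) and 0-based
# coordinates (P x 2), columns in raster (column-major) order
img_consts <- function(pixels) {
  d <- dim(pixels)
  P <- d[1] * d[2]
  Fm <- matrix(pixels, P, d[3])
  p <- seq_len(P) - 1L
  Cm <- cbind(p %% d[1], p %/% d[1])
  list(Fc = sx_const(Fm), Cc = sx_const(Cm), P = P, H = d[1], W = d[2])
}

# (H,W,NS) association array -> (NS x P) constant tensor
q_as_tensor <- function(q) {
  d <- dim(q)
  sx_const(t(matrix(q, d[1] * d[2], d[3])))
}

# unsquared Euclidean row norms of a (P x k) difference tensor, summed
row_norm_sum <- function(diff) {
  k <- ncol(diff$value)
  s2 <- sx_matmul(sx_mul(diff, diff), sx_const(matrix(1, k, 1)))
  sx_sum(sx_sqrt_smooth(s2))
}

# tensor-level superpixel loss for one image; Qt is the (NS x P) association
# tensor, ic the img_consts() of the slice
spixel_loss_core <- function(ic, Qt, m) {
  NS <- nrow(Qt$value)
  onesP <- sx_const(matrix(1, ic$P, 1))
  mass <- sx_add(sx_matmul(Qt, onesP), 1e-12)
  U <- sx_div_rows(sx_matmul(Qt, ic$Fc), mass)
  L <- sx_div_rows(sx_matmul(Qt, ic$Cc), mass)
  Qtt <- sx_transpose(Qt)
  intensity <- row_norm_sum(sx_sub(ic$Fc, sx_matmul(Qtt, U)))
  position <- row_norm_sum(sx_sub(ic$Cc, sx_matmul(Qtt, L)))
  list(total = sx_add(intensity, sx_mul(position, m)),
       intensity = intensity, position = position)
}

# tensor-level seed loss for one image; ht is the (P x 1) heatmap tensor
seed_loss_core <- function(ht, seeds, eps) {
  ip <- which(seeds$positive != 0)
  im <- which(seeds$negative != 0)
  denom <- length(ip) + length(im)
  if (denom == 0L) {
    warning("seed map has no seeded pixels; seed loss is 0")
    return(sx_const(0))
  }
  total <- sx_const(0)
  if (length(ip))
    total <- sx_add(total, sx_sum(sx_log(sx_clamp_min(sx_gather_rows(ht, ip), eps))))
  if (length(im)) {
    hneg <- sx_add(sx_mul(sx_gather_rows(ht, im), -1), 1)
    total <- sx_add(total, sx_sum(sx_log(sx_clamp_min(hneg, eps))))
  }
  sx_mul(total, -1 / denom)
}

#' Soft superpixel moments
#'
#' Mass (soft pixel count), mean intensity, and mean location of every
#' superpixel under the soft associations.  Zero-mass superpixels receive
#' zero moments.  Masses always sum to H * W.
#'
#' @param pixels an (H, W, 4) slice array
#' @param q the matching (H, W, N_S) association array
#' @return list with `u` (N_S x 4 mean intensities), `l` (N_S x 2 mean
#'   0-based (row, col) locations), `mass` (length N_S)
#' @export
superpixel_moments <- function(pixels, q) {
  ic <- img_consts(pixels)
  Qm <- t(matrix(q, ic$P, dim(q)[3]))  # NS x P
  mass <- rowSums(Qm)
  safe <- pmax(mass, 1e-12)
  u <- (Qm %*% ic$Fc$value) / safe
  l <- (Qm %*% ic$Cc$value) / safe
  u[mass == 0, ] <- 0
  l[mass == 0, ] <- 0
  list(u = u, l = l, mass = mass)
}

#' Superpixel compactness/intensity loss
#'
#' @param pixels an (H, W, 4) slice array
#' @param q the matching (H, W, N_S) association array
#' @param m superpixel-size coefficient (default 3/160)
#' @param parts if TRUE, return the intensity and position terms separately
#' @return the scalar loss, or a named list when `parts = TRUE`
#' @export
spixel_loss <- function(pixels, q, m = 3 / 160, parts = FALSE) {
  out <- sx_no_grad(spixel_loss_core(img_consts(pixels), q_as_tensor(q), m))
  if (parts)
    list(total = as.numeric(out$total$value),
         intensity = as.numeric(out$intensity$value),
         position = as.numeric(out$position$value))
  else as.numeric(out$total$value)
}

#' Seeding loss
#'
#' Cross-entropy of the tumor heatmap against the positive/negative seeds,
#' normalized by the total seeded pixel count.  Zero iff the heatmap is 1 on
#' every positive seed and 0 on every negative seed; equals log(2) for a
#' constant 0.5 heatmap.
#'
#' @param h_plus an (H, W) tumor-probability matrix in \[0, 1\]
#' @param seeds a [seed_map()] of matching shape
#' @param eps log floor (default 1e-7)
#' @return scalar loss (0 with a warning when no pixel is seeded)
#' @export
seed_loss <- function(h_plus, seeds, eps = 1e-7) {
  stopifnot(identical(dim(h_plus), dim(seeds$positive)))
  ht <- sx_const(matrix(as.vector(h_plus), ncol = 1))
  as.numeric(sx_no_grad(seed_loss_core(ht, seeds, eps))$value)
}

#' Combined training objective for one image
#'
#' `L = L_spixel + alpha * L_seed`, with the tumor heatmap computed from the
#' associations and superpixel scores as in [soft_cluster_heatmap()].
#'
#' @param pixels an (H, W, 4) slice array
#' @param q the (H, W, N_S) association array
#' @param r the length-N_S superpixel score vector
#' @param seeds a [seed_map()]
#' @param config a [loss_config()]
#' @return scalar loss
#' @export
combined_loss <- function(pixels, q, r, seeds, config = loss_config()) {
  ic <- img_consts(pixels)
  Qt <- q_as_tensor(q)
  out <- sx_no_grad({
    sp <- spixel_loss_core(ic, Qt, config$m)
    ht <- sx_matmul(sx_transpose(Qt), sx_const(matrix(r, ncol = 1)))
    sd_ <- seed_loss_core(ht, seeds, config$eps)
    sx_add(sp$total, sx_mul(sd_, config$alpha))
  })
  as.numeric(out$value)
}
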