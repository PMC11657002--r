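# Training objective: superpixel moments, compactness loss, seeding loss,
# combination, and end-to-end differentiability.

sx <- function(name) get(name, envir = asNamespace("spixelseg"))

# hard left/right partition of an (H, W) grid into 2 superpixels
halves_q <- function(H, W, NS = 2L) {
  q <- array(0, c(H, W, NS))
  q[, 1:(W / 2), 1] <- 1
  q[, (W / 2 + 1):W, 2] <- 1
  q
}

test_that("superpixel moments are soft-weighted means with conserved mass", {
  H <- 8; W <- 8
  # uniform q over a constant image: every mean intensity is the constant
  qu <- array(1 / 4, c(H, W, 4))
  px <- array(0.3, c(H, W, 4))
  mo <- superpixel_moments(px, qu)
  expect_equal(mo$u, matrix(0.3, 4, 4))
  expect_equal(sum(mo$mass), H * W, tolerance = 1e-4)

  # one-hot halves: locations are each half's centroid (0-based coords)
  qh <- halves_q(H, W)
  mo2 <- superpixel_moments(px, qh)
  expect_equal(mo2$l[1, ], c(3.5, 1.5))  # rows 0..7, cols 0..3
  expect_equal(mo2$l[2, ], c(3.5, 5.5))
  expect_equal(sum(mo2$mass), H * W)

  # zero-mass superpixels get zero moments
  q3 <- array(0, c(H, W, 3))
  q3[, , 1] <- 1
  mo3 <- superpixel_moments(px, q3)
  expect_equal(mo3$mass[2:3], c(0, 0))
  expect_equal(mo3$u[2, ], rep(0, 4))
})

test_that("spixel_loss vanishes on perfectly reconstructed blocks and prices spread", {
  H <- 8; W <- 8
  # piecewise-constant image matching a hard 2-block partition
  px <- array(0, c(H, W, 4))
  px[, 1:4, ] <- 0.2
  px[, 5:8, ] <- 0.8
  qh <- halves_q(H, W)
  m <- 3 / 160
  parts <- spixel_loss(px, qh, m = m, parts = TRUE)
  expect_equal(parts$intensity, 0, tolerance = 1e-9)
  # independent closed-form oracle: sum over pixels of distance to the
  # block centroid, identical blocks -> 2 * (one block's sum)
  rows <- rep(0:7, 4); cols <- rep(0:3, each = 8)
  block_sum <- sum(sqrt((rows - 3.5)^2 + (cols - 1.5)^2))
  expect_equal(parts$position, 2 * block_sum, tolerance = 1e-6)
  expect_equal(parts$total, m * 2 * block_sum, tolerance = 1e-6)

  # constant image, single active superpixel: intensity term is 0
  pc <- array(0.5, c(H, W, 4))
  q1 <- array(0, c(H, W, 2)); q1[, , 1] <- 1
  expect_equal(spixel_loss(pc, q1, parts = TRUE)$intensity, 0, tolerance = 1e-9)

  # non-negative on random inputs; position term scales linearly in m
  set.seed(71)
  raw <- array(rexp(H * W * 3), c(H, W, 3))
  qr <- raw / rep(apply(raw, c(1, 2), sum), times = 3)
  pr <- array(runif(H * W * 4), c(H, W, 4))
  l1 <- spixel_loss(pr, qr, m = 0.01, parts = TRUE)
  l2 <- spixel_loss(pr, qr, m = 0.02, parts = TRUE)
  expect_gte(l1$total, 0)
  expect_equal(l2$total - l2$intensity, 2 * (l1$total - l1$intensity),
               tolerance = 1e-8)
  expect_equal(l1$intensity, l2$intensity)
})

test_that("seed_loss hits its closed-form limit cases", {
  H <- 10; W <- 10
  sm <- seeds_from_heatmap(matrix(seq_len(H * W), H, W), 0.2)
  # perfect heatmap: 1 on positives, 0 on negatives
  h <- matrix(0.5, H, W)
  h[sm$positive == 1] <- 1
  h[sm$negative == 1] <- 0
  expect_equal(seed_loss(h, sm), 0)
  # constant 0.5 heatmap: exactly log 2
  expect_equal(seed_loss(matrix(0.5, H, W), sm), log(2), tolerance = 1e-12)
  # healthy override with an all-zero heatmap: 0
  ov <- apply_healthy_override(sm, 0L)
  expect_equal(seed_loss(matrix(0, H, W), ov), 0)
  # unseeded map warns and returns 0
  empty <- seed_map(matrix(0, H, W), matrix(0, H, W))
  expect_warning(v <- seed_loss(h, empty), "no seeded")
  expect_equal(v, 0)
  # eps floor keeps the loss finite on pathological heatmaps
  expect_true(is.finite(seed_loss(matrix(0, H, W), sm)))
})

test_that("combined_loss is the alpha-weighted sum of its terms", {
  set.seed(72)
  H <- 8; W <- 8; NS <- 4
  raw <- array(rexp(H * W * NS), c(H, W, NS))
  q <- raw / rep(apply(raw, c(1, 2), sum), times = NS)
  r <- as.vector(rexp(NS)); r <- r / sum(r)
  px <- array(runif(H * W * 4), c(H, W, 4))
  sm <- seeds_from_heatmap(matrix(rnorm(H * W), H, W), 0.2)
  l0 <- combined_loss(px, q, r, sm, loss_config(alpha = 0))
  expect_equal(l0, spixel_loss(px, q, m = 3 / 160), tolerance = 1e-10)
  la <- combined_loss(px, q, r, sm, loss_config(alpha = 50))
  l2a <- combined_loss(px, q, r, sm, loss_config(alpha = 100))
  # doubling alpha doubles the seed contribution
  expect_equal(l2a - l0, 2 * (la - l0), tolerance = 1e-8)
  h <- soft_cluster_heatmap(q, r)
  expect_equal(la, l0 + 50 * seed_loss(h, sm), tolerance = 1e-8)
})

test_that("combined loss gradients through q and r match finite differences", {
  set.seed(73)
  H <- 8; W <- 8; NS <- 3
  px <- array(runif(H * W * 4), c(H, W, 4, 1))
  sm <- seeds_from_heatmap(matrix(rnorm(H * W), H, W), 0.2)
  lc <- loss_config(alpha = 5)
  zq <- sx("sx_param")(array(rnorm(H * W * NS, sd = 0.5), c(H, W, NS, 1)))
  zr <- sx("sx_param")(matrix(rnorm(NS, sd = 0.5), 1, NS))
  loss_of <- function() {
    sx("sx_tape_reset")()
    qt <- sx("sx_softmax_channels")(zq)
    rt <- sx("sx_softmax_rows")(zr)
    ic <- sx("img_consts")(px[, , , 1])
    Qj <- sx("sx_img_mat")(qt, 1L)
    sp <- sx("spixel_loss_core")(ic, Qj, lc$m)
    hj <- sx("sx_matmul")(sx("sx_transpose")(Qj),
                          sx("sx_transpose")(sx("sx_row")(rt, 1L)))
    sl <- sx("seed_loss_core")(hj, sm, lc$eps)
    sx("sx_add")(sp$total, sx("sx_mul")(sl, lc$alpha))
  }
  l0 <- loss_of()
  sx("sx_zero_grads")(list(zq, zr))
  sx("sx_backward")(l0)
  for (p in list(zq, zr)) {
    expect_false(is.null(p$grad))
    for (k in sample(length(p$value), min(4, length(p$value)))) {
      eps <- 1e-5
      old <- p$value[k]
      p$value[k] <- old + eps; fp <- as.numeric(loss_of()$value)
      p$value[k] <- old - eps; fm <- as.numeric(loss_of()$value)
      p$value[k] <- old
      fd <- (fp - fm) / (2 * eps)
      expect_equal(p$grad[k], fd, tolerance = 1e-3)
    }
  }
})

test_that("one small gradient step strictly decreases the combined loss", {
  set.seed(74)
  H <- 8; W <- 8; NS <- 3
  px <- array(runif(H * W * 4), c(H, W, 4, 1))
  sm <- seeds_from_heatmap(matrix(rnorm(H * W), H, W), 0.2)
  lc <- loss_config(alpha = 5)
  zq <- sx("sx_param")(array(rnorm(H * W * NS, sd = 0.5), c(H, W, NS, 1)))
  zr <- sx("sx_param")(matrix(rnorm(NS, sd = 0.5), 1, NS))
  loss_of <- function() {
    sx("sx_tape_reset")()
    qt <- sx("sx_softmax_channels")(zq)
    rt <- sx("sx_softmax_rows")(zr)
    ic <- sx("img_consts")(px[, , , 1])
    Qj <- sx("sx_img_mat")(qt, 1L)
    sp <- sx("spixel_loss_core")(ic, Qj, lc$m)
    hj <- sx("sx_matmul")(sx("sx_transpose")(Qj),
                          sx("sx_transpose")(sx("sx_row")(rt, 1L)))
    sl <- sx("seed_loss_core")(hj, sm, lc$eps)
    sx("sx_add")(sp$total, sx("sx_mul")(sl, lc$alpha))
  }
  l0 <- loss_of()
  sx("sx_zero_grads")(list(zq, zr))
  sx("sx_backward")(l0)
  lr <- 1e-4
  zq$value <- zq$value - lr * zq$grad
  zr$value <- zr$value - lr * zr$grad
  expect_lt(as.numeric(loss_of()$value), as.numeric(l0$value))
})
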