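# Soft clustering, threshold selection, and gated segmentation.

simplex_q <- function(H, W, NS, seed = 1) {
  set.seed(seed)
  raw <- array(rexp(H * W * NS), c(H, W, NS))
  raw / rep(apply(raw, c(1, 2), sum), times = NS)
}

test_that("soft_cluster_heatmap matches its selection and convex-combination forms", {
  H <- 8; W <- 8; NS <- 5
  q <- simplex_q(H, W, NS, seed = 81)
  # one-hot scores select the corresponding association map
  r1 <- rep(0, NS); r1[3] <- 1
  expect_equal(soft_cluster_heatmap(q, r1), q[, , 3], tolerance = 1e-12)
  # uniform associations collapse to 1 / N_S everywhere
  qu <- array(1 / NS, c(H, W, NS))
  r <- rexp(NS); r <- r / sum(r)
  expect_equal(soft_cluster_heatmap(qu, r), matrix(1 / NS, H, W),
               tolerance = 1e-12)
  # hard partition: every pixel takes the score of its superpixel
  qh <- array(0, c(H, W, NS))
  lab <- matrix(sample(1:NS, H * W, replace = TRUE), H, W)
  for (s in 1:NS) qh[, , s] <- (lab == s) * 1
  expect_equal(soft_cluster_heatmap(qh, r), matrix(r[lab], H, W),
               tolerance = 1e-12)
  # range and conservation invariants
  h <- soft_cluster_heatmap(q, r)
  expect_true(all(h >= 0 & h <= 1))
  expect_equal(mean(h), sum(r * apply(q, 3, mean)), tolerance = 1e-12)
})

test_that("select_threshold maximizes validation Dice with ties to the larger value", {
  # binary heatmaps: every threshold on the grid ties -> 0.9 by the tie rule
  H <- 6; W <- 6
  hb <- array(0, c(H, W, 2))
  hb[2:4, 2:4, 1] <- 1
  refs <- hb
  expect_equal(select_threshold(hb, refs), 0.9)
  # constructed heatmap whose reference is {h > 0.35}: only 0.4 recovers it
  hv <- array(0.3, c(H, W, 1))
  hv[2:3, 2:3, 1] <- 0.45
  hv[4:5, 4:5, 1] <- 0.7
  ref2 <- (hv > 0.35) * 1
  expect_equal(select_threshold(hv, ref2), 0.4)
  expect_error(select_threshold(array(0, c(H, W, 0)), array(0, c(H, W, 0))),
               "empty")
  # unsupervised fallback never inspects the masks
  expect_equal(select_threshold(hv, ref2, unsupervised = TRUE), 0.5)
})

test_that("segmentation applies the classifier gate and >= threshold rule", {
  gen <- new_superpixel_generator(6L, width = 4L, rng_seed = 82L)
  clu <- new_superpixel_clusterer(6L, backbone = "small", width = 4L,
                                  rng_seed = 83L)
  set.seed(84)
  x <- array(runif(16 * 16 * 4), c(16, 16, 4))
  s0 <- segment_slice(x, gen, clu, classifier = NULL, threshold = 0)
  expect_equal(sum(s0$mask), 16 * 16)  # threshold 0 segments everything
  # threshold above every heatmap value yields an empty mask
  s1 <- segment_slice(x, gen, clu, classifier = NULL,
                      threshold = max(s0$heatmap) + 0.05)
  expect_equal(sum(s1$mask), 0)
  # threshold exactly at a value keeps it (>= convention)
  tmax <- max(s0$heatmap)
  s2 <- segment_slice(x, gen, clu, classifier = NULL, threshold = tmax)
  expect_gte(sum(s2$mask), 1)
  expect_true(all(s2$mask[s0$heatmap == tmax] == 1))
})

test_that("raising the threshold yields nested masks", {
  gen <- new_superpixel_generator(6L, width = 4L, rng_seed = 85L)
  clu <- new_superpixel_clusterer(6L, backbone = "small", width = 4L,
                                  rng_seed = 86L)
  set.seed(87)
  x <- array(runif(16 * 16 * 4), c(16, 16, 4))
  prev <- NULL
  for (t in seq(0.1, 0.9, by = 0.1)) {
    m <- segment_slice(x, gen, clu, classifier = NULL, threshold = t)$mask
    if (!is.null(prev)) expect_true(all(m <= prev))
    prev <- m
  }
})

test_that("predicted-healthy slices receive empty masks regardless of the heatmap", {
  co <- easy_cohorts()
  model <- toy_classifier()
  gen <- new_superpixel_generator(6L, width = 4L, rng_seed = 88L)
  clu <- new_superpixel_clusterer(6L, backbone = "small", width = 4L,
                                  rng_seed = 89L)
  sub <- ds_subset(co$val, 1:10)
  out <- segment_dataset(sub, gen, clu, model, threshold = 0)
  # threshold 0 would segment every pixel, so any empty mask is gate-forced
  for (i in 1:10) {
    if (out$gate[i] == 0L) expect_equal(sum(out$masks[, , i]), 0)
    else expect_equal(sum(out$masks[, , i]), 32 * 32)
  }
  expect_equal(out$gate,
               as.integer(predict_tumor_probability(model, sub) >= 0.5))
})
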