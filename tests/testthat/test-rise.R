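# RISE mask generation, saliency heatmaps, and quantile seed extraction.

test_that("mask sets are reproducible and match the keep probability", {
  m1 <- generate_masks(c(16, 16), K = 400L, cell_grid = 4L, keep_prob = 0.5,
                       rng_seed = 9L)
  m2 <- generate_masks(c(16, 16), K = 400L, cell_grid = 4L, keep_prob = 0.5,
                       rng_seed = 9L)
  expect_identical(m1$masks, m2$masks)
  expect_true(all(m1$masks >= 0 & m1$masks <= 1))
  # Monte-Carlo mean within 3 standard errors of the Bernoulli mean
  mean_per_mask <- apply(m1$masks, 3, mean)
  se <- sd(mean_per_mask) / sqrt(length(mean_per_mask))
  expect_lt(abs(mean(mean_per_mask) - 0.5), 3 * se + 1e-3)
  expect_error(generate_masks(c(16, 16), K = 10L, keep_prob = 0),
               "keep_prob")
  expect_error(generate_masks(c(16, 16), K = 0L), "K must be positive")
})

test_that("constant classifiers give the closed-form heatmap", {
  masks <- generate_masks(c(12, 12), K = 200L, cell_grid = 4L, rng_seed = 10L)
  zero_fn <- function(x) rep(0, dim(x)[4])
  h0 <- rise_heatmap(zero_fn, array(0.5, c(12, 12, 4)), masks)
  expect_equal(h0, matrix(0, 12, 12))
  const_fn <- function(x) rep(0.7, dim(x)[4])
  hc <- rise_heatmap(const_fn, array(0.5, c(12, 12, 4)), masks)
  closed <- 0.7 * apply(masks$masks, c(1, 2), sum) / (masks$K * masks$keep_prob)
  expect_equal(hc, closed, tolerance = 1e-12)
})

test_that("heatmap is linear in the classifier score", {
  masks <- generate_masks(c(12, 12), K = 150L, cell_grid = 4L, rng_seed = 12L)
  x <- array(runif(12 * 12 * 4), c(12, 12, 4))
  f <- function(xb) apply(xb, 4, function(img) mean(img[3:6, 3:6, 4]))
  ones_fn <- function(xb) rep(1, dim(xb)[4])
  alpha <- 0.6; beta <- 0.2
  g <- function(xb) alpha * f(xb) + beta * ones_fn(xb)
  hg <- rise_heatmap(g, x, masks)
  hf <- rise_heatmap(f, x, masks)
  h1 <- rise_heatmap(ones_fn, x, masks)
  expect_equal(hg, alpha * hf + beta * h1, tolerance = 1e-10)
})

test_that("an analytic box-mean classifier localizes the box", {
  # toy "classifier": mean intensity inside a known box; the saliency argmax
  # must fall inside that box
  H <- 16
  box <- c(5, 9, 6, 10)  # rows 5:9, cols 6:10
  x <- array(1, c(H, H, 4))
  f <- function(xb) apply(xb, 4, function(img)
    mean(img[box[1]:box[2], box[3]:box[4], ]))
  masks <- generate_masks(c(H, H), K = 2000L, cell_grid = 4L, rng_seed = 13L)
  h <- rise_heatmap(f, x, masks)
  am <- which(h == max(h), arr.ind = TRUE)[1, ]
  expect_gte(am["row"], box[1]); expect_lte(am["row"], box[2])
  expect_gte(am["col"], box[3]); expect_lte(am["col"], box[4])
})

test_that("seed counts follow the 20% rule with stable raster tie-breaking", {
  set.seed(14)
  h <- matrix(sample(seq_len(128 * 128)), 128, 128)  # distinct values
  sm <- seeds_from_heatmap(h, 0.2)
  expect_equal(sum(sm$positive), round(0.2 * 16384))  # 3277
  expect_equal(sum(sm$negative), 3277)
  expect_equal(sum(sm$positive * sm$negative), 0)

  # strictly increasing raster heatmap: bottom 20% first, top 20% last
  hr <- matrix(seq_len(100) / 100, 10, 10)
  s2 <- seeds_from_heatmap(hr, 0.2)
  expect_equal(which(s2$negative == 1), 1:20)
  expect_equal(which(s2$positive == 1), 81:100)

  # constant heatmap: raster order fills negatives first, positives last
  s3 <- seeds_from_heatmap(matrix(1, 10, 10), 0.2)
  expect_equal(which(s3$negative == 1), 1:20)
  expect_equal(which(s3$positive == 1), 81:100)

  expect_error(seeds_from_heatmap(matrix(1, 3, 3)), "too small")
})

test_that("seed maps depend only on heatmap ranks", {
  set.seed(15)
  h <- matrix(runif(400), 20, 20)
  s1 <- seeds_from_heatmap(h)
  s2 <- seeds_from_heatmap(matrix(exp(3 * h), 20, 20))  # monotone transform
  expect_identical(s1$positive, s2$positive)
  expect_identical(s1$negative, s2$negative)
})

test_that("seed maps always satisfy the disjointness invariant", {
  set.seed(16)
  for (trial in 1:20) {
    H <- sample(4:12, 1) * 2; W <- sample(4:12, 1) * 2
    sm <- seeds_from_heatmap(matrix(rnorm(H * W), H, W),
                             quantile = runif(1, 0.05, 0.45))
    expect_equal(sum(sm$positive * sm$negative), 0)
    expect_lte(sum(sm$positive) + sum(sm$negative), H * W)
  }
})

test_that("the healthy override replaces seeds with all-negatives and is idempotent", {
  sm <- seeds_from_heatmap(matrix(runif(144), 12, 12))
  ov <- apply_healthy_override(sm, 0L)
  expect_equal(sum(ov$positive), 0)
  expect_equal(sum(ov$negative), 144)
  ov2 <- apply_healthy_override(ov, 0L)
  expect_identical(ov$negative, ov2$negative)
  expect_identical(apply_healthy_override(sm, 1L), sm)
})

test_that("make_seeds overrides exactly the predicted-healthy slices", {
  co <- easy_cohorts()
  model <- toy_classifier()
  sub <- ds_subset(co$val, 1:8)
  masks <- generate_masks(dim(sub$pixels)[1:2], K = 60L, rng_seed = 17L)
  out <- make_seeds(model, sub, masks)
  for (i in seq_len(8)) {
    if (out$predicted[i] == 0L) {
      expect_equal(sum(out$seeds[[i]]$positive), 0)
      expect_equal(sum(out$seeds[[i]]$negative), length(out$seeds[[i]]$negative))
    } else {
      expect_equal(sum(out$seeds[[i]]$positive), round(0.2 * 32 * 32))
    }
  }
})
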