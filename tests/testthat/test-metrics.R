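# Dice / U-Dice / HD95 conventions and brute-force oracle equivalence.

test_that("dice follows the smoothed overlap formula and its limit cases", {
  z <- matrix(0, 4, 4)
  expect_equal(dice(z, z), 1)  # empty-vs-empty via smoothing
  a <- z; a[1:2, 1:2] <- 1
  expect_equal(dice(a, a), 1)
  a2 <- z; a2[1, 1:2] <- 1
  b2 <- z; b2[1:2, 1] <- 1
  expect_equal(dice(a2, b2), 3 / 5)  # |A|=2, |B|=2, |A∩B|=1
  expect_equal(dice(a2, b2), dice(b2, a2))
  expect_error(dice(z, matrix(0, 3, 3)), "shape")
})

test_that("u_dice rewards undersegmentation and is asymmetric", {
  z <- matrix(0, 4, 4)
  b <- z; b[1:3, 1:3] <- 1
  expect_equal(u_dice(z, b), 0)  # empty proposal, non-empty truth
  a <- z; a[1:2, 1:2] <- 1       # |A|=4, subset of B
  expect_equal(u_dice(a, b), 1)
  expect_equal(u_dice(z, z), 1)  # both empty, smoothing
  a2 <- z; a2[1, 1:2] <- 1
  b2 <- z; b2[1, 2] <- 1; b2[4, 4] <- 1
  expect_equal(u_dice(a2, b2), 2 / 3)  # |A|=2, |A∩B|=1
  # asymmetric: a small subset scores 1 forward, 0.2 backward
  s <- z; s[2, 2] <- 1
  expect_equal(u_dice(s, b), 1)
  expect_equal(u_dice(b, s), (1 + 1) / (9 + 1))
})

test_that("hd95 honors the empty-mask and identity conventions", {
  z <- matrix(0, 8, 8)
  a <- z; a[3:5, 3:5] <- 1
  expect_equal(hd95(z, a), 0)
  expect_equal(hd95(a, z), 0)
  expect_equal(hd95(z, z), 0)
  expect_equal(hd95(a, a), 0)
  p1 <- z; p1[1, 1] <- 1
  p2 <- z; p2[4, 5] <- 1  # offset (3, 4) -> distance 5
  expect_equal(hd95(p1, p2), 5)
  expect_gte(hd95(p2, p1, symmetric = TRUE), hd95(p2, p1))
})

test_that("dice and u_dice match brute-force set arithmetic on all 3x3 mask pairs", {
  masks <- lapply(0:511, function(k) matrix(as.integer(bitwAnd(k, 2^(0:8)) > 0), 3, 3))
  worst <- 0
  for (i in seq_along(masks)) {
    a <- masks[[i]]
    for (j in seq_along(masks)) {
      b <- masks[[j]]
      worst <- max(worst,
                   abs(dice(a, b) - oracle_dice(a, b)),
                   abs(u_dice(a, b) - oracle_u_dice(a, b)))
    }
  }
  expect_identical(worst, 0)
})

test_that("hd95 matches all-pairs brute force on random small masks", {
  set.seed(11)
  for (trial in seq_len(1000)) {
    H <- sample(2:8, 1); W <- sample(2:8, 1)
    a <- rand_mask(H, W); b <- rand_mask(H, W)
    expect_equal(hd95(a, b), oracle_hd95(a, b), tolerance = 1e-12)
  }
})

test_that("evaluate_cohort aggregates per-image metrics with stratified means", {
  set.seed(3)
  refs <- array(0, c(6, 6, 3))
  refs[2:4, 2:4, 1] <- 1
  refs[1:2, 1:2, 2] <- 1
  preds <- refs
  preds[, , 3] <- 0
  res <- evaluate_cohort(preds, refs, classifier_correct = c(TRUE, TRUE, FALSE))
  expect_equal(nrow(res$per_image), 3)
  expect_equal(res$per_image$dice, c(1, 1, 1))  # image 3: both empty
  # stratification partitions the cohort
  ns <- res$summary$n[match(c("correct", "incorrect"), res$summary$stratum)]
  expect_equal(sum(ns), res$summary$n[res$summary$stratum == "all"])
  # hand-computed means on a fixture with a known error
  preds2 <- preds
  preds2[2:4, 2:4, 1] <- 0
  preds2[2, 2, 1] <- 1  # |A|=1 subset of |B|=9
  res2 <- evaluate_cohort(preds2, refs)
  hand <- mean(c((2 * 1 + 1) / (1 + 9 + 1), 1, 1))
  expect_equal(res2$summary$mean_dice[res2$summary$stratum == "all"], hand)
  expect_error(evaluate_cohort(preds, refs[, , 1:2]), "shape|count")
})

test_that("perfect segmentations score mean dice 1 and mean hd95 0", {
  set.seed(4)
  refs <- array(rbinom(5 * 5 * 4, 1, 0.3), c(5, 5, 4))
  res <- evaluate_cohort(refs, refs)
  expect_equal(res$summary$mean_dice[1], 1)
  expect_equal(res$summary$mean_hd95[1], 0)
})
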