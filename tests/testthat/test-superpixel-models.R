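# Forward contracts of the superpixel generation and clustering networks.

test_that("association maps are per-pixel simplexes at full input resolution", {
  gen <- new_superpixel_generator(8L, width = 4L, rng_seed = 51L)
  set.seed(52)
  for (trial in 1:5) {
    H <- sample(c(16L, 24L, 32L), 1)
    x <- array(runif(H * H * 4), c(H, H, 4))
    q <- generator_forward(gen, x)
    expect_equal(dim(q), c(H, H, 8))
    sums <- apply(q, c(1, 2), sum)
    expect_lt(max(abs(sums - 1)), 1e-5)
    expect_gte(min(q), 0)
  }
})

test_that("the generator rejects resolutions its downsampling cannot divide", {
  gen <- new_superpixel_generator(8L, width = 4L, rng_seed = 53L)
  expect_error(generator_forward(gen, array(0.5, c(18, 18, 4))),
               "divisible by 4")
})

test_that("different inputs give different associations (non-degeneracy)", {
  gen <- new_superpixel_generator(8L, width = 4L, rng_seed = 54L)
  set.seed(55)
  x1 <- array(runif(16 * 16 * 4), c(16, 16, 4))
  x2 <- array(runif(16 * 16 * 4), c(16, 16, 4))
  expect_gt(max(abs(generator_forward(gen, x1) - generator_forward(gen, x2))),
            1e-4)
})

test_that("associations are approximately equivariant to stride translations", {
  gen <- new_superpixel_generator(8L, width = 4L, rng_seed = 56L)
  set.seed(57)
  H <- 24; shift <- 4  # total downsampling factor of the network
  x <- array(runif(H * H * 4), c(H, H, 4))
  xs <- array(0, c(H, H, 4))
  xs[(shift + 1):H, , ] <- x[1:(H - shift), , ]
  q <- generator_forward(gen, x)
  qs <- generator_forward(gen, xs)
  # compare away from the padded border: q shifted down by `shift` should
  # approximate qs; correlation is the documented tolerance (> 0.8)
  inner <- (shift + 3):(H - 2)
  a <- q[inner - shift, 3:(H - 2), ]
  b <- qs[inner, 3:(H - 2), ]
  expect_gt(cor(as.vector(a), as.vector(b)), 0.8)
})

test_that("superpixel scores are a simplex, deterministic, and q-sensitive", {
  clu <- new_superpixel_clusterer(8L, backbone = "small", width = 4L,
                                  rng_seed = 58L)
  gen <- new_superpixel_generator(8L, width = 4L, rng_seed = 59L)
  set.seed(60)
  x <- array(runif(16 * 16 * 4), c(16, 16, 4))
  q <- generator_forward(gen, x)
  r <- cluster_forward(clu, x, q)
  expect_length(r, 8)
  expect_lt(abs(sum(r) - 1), 1e-5)
  expect_gte(min(r), 0)
  expect_identical(r, cluster_forward(clu, x, q))  # eval-mode determinism
  # permuting the association channels changes the scores
  qp <- q[, , c(3, 1, 2, 5, 4, 7, 8, 6)]
  expect_gt(max(abs(r - cluster_forward(clu, x, qp))), 1e-6)
  # head mismatch is caught
  expect_error(cluster_forward(clu, x, q[, , 1:5]), "expects")
})

test_that("count_effective_superpixels follows the argmax-with-lowest-index rule", {
  q_unif <- array(1 / 6, c(8, 8, 6))
  expect_equal(count_effective_superpixels(q_unif), 1)  # ties -> index 1
  # one-hot partition using 5 of 10 superpixels
  q <- array(0, c(10, 10, 10))
  lab <- matrix(rep(c(1, 3, 5, 7, 9), each = 20), 10, 10)
  for (s in 1:10) q[, , s] <- (lab == s) * 1
  expect_equal(count_effective_superpixels(q), 5)
  expect_equal(sort(unique(as.vector(superpixel_labels(q)))), c(1, 3, 5, 7, 9))
  # pigeonhole bounds over random simplexes
  set.seed(61)
  for (trial in 1:10) {
    raw <- array(rexp(6 * 6 * 4), c(6, 6, 4))
    qr <- raw / rep(apply(raw, c(1, 2), sum), times = 4)
    n <- count_effective_superpixels(qr)
    expect_gte(n, 1); expect_lte(n, 4)
  }
})

test_that("simplex invariants hold across repeated random forward passes", {
  gen <- new_superpixel_generator(6L, width = 4L, rng_seed = 62L)
  clu <- new_superpixel_clusterer(6L, backbone = "small", width = 4L,
                                  rng_seed = 63L)
  set.seed(64)
  for (trial in 1:10) {
    x <- array(runif(16 * 16 * 4 * 2), c(16, 16, 4, 2))
    q <- generator_forward(gen, x)
    r <- cluster_forward(clu, x, q)
    expect_lt(max(abs(apply(q, c(1, 2, 4), sum) - 1)), 1e-5)
    expect_lt(max(abs(rowSums(r) - 1)), 1e-5)
  }
})
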