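# Shared fixtures: small phantom cohorts and a lazily trained toy
# classifier, cached for the session so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, compute) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- compute()
  .fixtures[[name]]
}

easy_cohorts <- function() {
  fixture("easy_cohorts", function() {
    pc <- phantom_difficulty_suite()$easy
    list(train = generate_phantom(pc, n_images = 96L, rng_seed = 201L),
         val = generate_phantom(pc, n_images = 32L, rng_seed = 202L),
         test = generate_phantom(pc, n_images = 32L, rng_seed = 203L))
  })
}

toy_classifier <- function() {
  fixture("toy_classifier", function() {
    co <- easy_cohorts()
    train_classifier(co$train, co$val,
                     classifier_config(backbone = "small", width = 6L,
                                       epochs = 4L, rng_seed = 7L))
  })
}

# independent brute-force metric oracles (plain set arithmetic / all-pairs
# distances; no shared code with the package implementations)
oracle_dice <- function(a, b, smooth = 1) {
  ia <- sum(a != 0 & b != 0)
  (2 * ia + smooth) / (sum(a != 0) + sum(b != 0) + smooth)
}

oracle_u_dice <- function(a, b, smooth = 1) {
  na <- sum(a != 0)
  if (na == 0 && sum(b != 0) > 0) return(0)
  (sum(a != 0 & b != 0) + smooth) / (na + smooth)
}

# boundary by explicit per-pixel neighbor inspection
oracle_boundary <- function(m) {
  m <- m != 0
  H <- nrow(m); W <- ncol(m)
  out <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!m[i, j]) next
    nb <- c(if (i > 1) m[i - 1, j] else FALSE,
            if (i < H) m[i + 1, j] else FALSE,
            if (j > 1) m[i, j - 1] else FALSE,
            if (j < W) m[i, j + 1] else FALSE)
    if (!all(nb)) out <- rbind(out, c(i, j))
  }
  out
}

oracle_hd95 <- function(a, b) {
  if (sum(a != 0) == 0 || sum(b != 0) == 0) return(0)
  ca <- oracle_boundary(a); cb <- oracle_boundary(b)
  dmin <- apply(ca, 1, function(p)
    min(sqrt((p[1] - cb[, 1])^2 + (p[2] - cb[, 2])^2)))
  # linear-interpolation 95th percentile on the sorted list
  s <- sort(dmin); n <- length(s)
  h <- 0.95 * (n - 1) + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

rand_mask <- function(H, W, p = 0.4) matrix(rbinom(H * W, 1, p), H, W)
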