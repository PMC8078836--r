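test_that("one-side sampling keeps top gradients and sizes subsets correctly", {
  g <- c(3, -5, 1, 0)
  s <- gossSample(g, a = 0.5, b = 0.5, seed = 1)
  expect_setequal(s$A, c(1, 2))          # |−5| and |3| are the two largest
  expect_equal(length(s$B), 1)           # ceil(0.5 * 2)
  expect_length(intersect(s$A, s$B), 0)

  full <- gossSample(g, a = 1, b = 0.5, seed = 1)
  expect_equal(full$A, 1:4)
  expect_length(full$B, 0)
  expect_equal(full$amplifier, 0)

  s100 <- gossSample(rnorm(100), a = 0.2, b = 0.1, seed = 3)
  expect_length(s100$A, 20)
  expect_length(s100$B, 8)
  expect_equal(s100$amplifier, 80 / 8)   # normalizes B back to |A^c|

  # deterministic given the seed; ties broken by ascending index
  expect_identical(gossSample(g, 0.5, 0.5, seed = 9),
                   gossSample(g, 0.5, 0.5, seed = 9))
  tie <- gossSample(c(2, 2, 2, 2), a = 0.5, b = 0, seed = 1)
  expect_equal(tie$A, c(1, 2))
})

test_that("estimated variance gain reduces to the exact gain when a = 1", {
  set.seed(12)
  g <- rnorm(12); x <- sample(1:6, 12, replace = TRUE) + runif(12) / 10
  s <- gossSample(g, a = 1, b = 0, seed = 1)
  for (d in splitCandidates(x)) {
    got <- gossVarianceGain(s, g, x, d)
    expect_equal(got$gain, oracleExactGain(g, x, d), tolerance = 1e-12)
    expect_equal(got$n_left + got$n_right, 12)
  }
  # all-zero gradients give zero gain at every split
  z <- rep(0, 12)
  sz <- gossSample(z, a = 1, b = 0, seed = 1)
  for (d in splitCandidates(x))
    expect_equal(gossVarianceGain(sz, z, x, d)$gain, 0)
  # an empty side is an invalid split
  expect_equal(gossVarianceGain(s, g, x, max(x) + 1)$gain, -Inf)
})

test_that("sampled gain matches a term-by-term evaluation of the formula", {
  set.seed(5)
  g <- rnorm(12); x <- runif(12)
  s <- gossSample(g, a = 0.5, b = 0.5, seed = 77)
  for (d in splitCandidates(x)) {
    got <- gossVarianceGain(s, g, x, d)$gain
    expect_equal(got, oracleGossGain(s$A, s$B, s$amplifier, g, x, d),
                 tolerance = 1e-12)
  }
})

test_that("the sampled gain estimator converges to the exact gain", {
  # one-side sampling's operating regime: the kept half carries the large
  # gradients, the sampled complement the small ones
  g <- c(5, 4.5, 4.8, -5.2, -4.7, -4.9, 0.1, -0.08, 0.05, 0.07, -0.03, 0.06)
  x <- c(1, 2, 3, 10, 11, 12, 4, 5, 6, 7, 8, 9)
  for (d in splitCandidates(x)) {
    exact <- oracleExactGain(g, x, d)
    gains <- vapply(1:250, function(seed) {
      s <- gossSample(g, a = 0.5, b = 0.5, seed = seed)
      gossVarianceGain(s, g, x, d)$gain
    }, numeric(1))
    expect_lt(abs(mean(gains) - exact) / abs(exact), 0.05)
  }
})

test_that("with a = 1 the best GOSS split equals the best exact split", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(10:50, 1)
    g <- rnorm(n)
    X <- cbind(runif(n), sample(1:4, n, replace = TRUE))
    s <- gossSample(g, a = 1, b = 0.3, seed = seed)
    for (j in 1:2) {
      cands <- splitCandidates(X[, j])
      goss <- vapply(cands, function(d) gossVarianceGain(s, g, X[, j], d)$gain,
                     numeric(1))
      exact <- vapply(cands, function(d) oracleExactGain(g, X[, j], d),
                      numeric(1))
      expect_equal(which.max(goss), which.max(exact))
    }
  }
})

test_that("greedy bundling respects the conflict budget exhaustively", {
  # perfectly exclusive features collapse into one bundle
  X <- diag(4)[rep(1:4, 2), ]
  b <- greedyBundle(X, K = 0)
  expect_length(b, 1)
  expect_setequal(b[[1]]$members, 1:4)

  # all-pairs conflicting features cannot share a bundle at K = 0
  Y <- matrix(1, 5, 3)
  b0 <- greedyBundle(Y, K = 0)
  expect_length(b0, 3)

  set.seed(19)
  Z <- matrix(rbinom(240, 1, 0.2), 30, 8)
  bz <- greedyBundle(Z, K = 2)
  for (bun in bz) {
    mem <- bun$members
    tot <- 0
    if (length(mem) > 1) {
      for (i in seq_along(mem)) for (j in seq_along(mem)) {
        if (i < j) tot <- tot + sum(Z[, mem[i]] != 0 & Z[, mem[j]] != 0)
      }
    }
    expect_lte(tot, 2)
    expect_equal(tot, bun$conflict_count)
  }
  expect_setequal(unlist(lapply(bz, `[[`, "members")), 1:8)
})

test_that("merging exclusive features is invertible on conflict-free rows", {
  X <- cbind(c(0, 1, 0, 0), c(1, 0, 0, 1))
  b <- list(members = 1:2, conflict_count = 0)
  m <- mergeExclusiveFeatures(b, X)
  expect_setequal(unique(m$merged), c(0, 1, 2))
  expect_equal(unname(decodeBundle(m)), X)

  # single-feature bundle is the identity
  ms <- mergeExclusiveFeatures(list(members = 2, conflict_count = 0), X)
  expect_equal(ms$merged, X[, 2])

  # random exclusive 3-feature bundle round-trips exactly
  set.seed(23)
  slot3 <- sample(1:3, 20, replace = TRUE)
  vals <- sample(1:3, 20, replace = TRUE) * rbinom(20, 1, 0.7)
  R <- matrix(0, 20, 3)
  R[cbind(1:20, slot3)] <- vals
  br <- greedyBundle(R, K = 0)
  expect_length(br, 1)
  mr <- mergeExclusiveFeatures(br[[1]], R)
  dec <- decodeBundle(mr)
  expect_equal(unname(dec[, order(as.integer(colnames(dec)))]), R)
  expect_true(all(diff(mr$offsets) > 0) || length(mr$offsets) == 1)
})
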