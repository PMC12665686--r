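test_that("full attention reduces to hand-computable cases", {
  # n = 1: softmax of a scalar is 1, output is V itself
  expect_equal(fullAttention(matrix(2, 1, 3), matrix(1, 1, 3),
                             matrix(5, 1, 3)),
               matrix(5, 1, 3))
  # identical keys: uniform weights, every row is the column mean of V
  withr::with_seed(1L, {
    Q <- matrix(rnorm(12), 4, 3)
    K <- matrix(rep(c(1, 0, -1), each = 4), 4, 3)
    K <- matrix(rep(K[1, ], 4), 4, 3, byrow = TRUE)
    V <- matrix(rnorm(12), 4, 3)
  })
  out <- fullAttention(Q, K, V)
  for (i in 1:4) expect_equal(out[i, ], colMeans(V), tolerance = 1e-12)
  # small integer case against a manual softmax-weighted sum
  Q <- rbind(c(1, 0), c(0, 1), c(1, 1))
  K <- rbind(c(1, 0), c(0, 2), c(1, 1))
  V <- rbind(c(1, 2), c(3, 4), c(5, 6))
  manual <- t(vapply(1:3, function(i) {
    s <- as.numeric(K %*% Q[i, ]) / sqrt(2)
    w <- exp(s - max(s)); w <- w / sum(w)
    as.numeric(t(V) %*% w)
  }, numeric(2)))
  expect_equal(fullAttention(Q, K, V), manual, tolerance = 1e-6)
  expect_error(fullAttention(matrix(NaN, 1, 1), matrix(1, 1, 1),
                             matrix(1, 1, 1)), "non-finite")
})

test_that("angular LSH hashing is scale-invariant, splits antipodes, and is seeded", {
  v <- matrix(rnorm(8), 2, 4)
  v[2, ] <- 2 * v[1, ]  # same direction, different scale
  h <- lshHash(v, nBuckets = 8L, nRounds = 5L, seed = 4L)
  expect_equal(h[1, ], h[2, ])
  x <- matrix(c(1, 2, -1, -2), 2, 2, byrow = TRUE)
  h2 <- lshHash(x, nBuckets = 2L, nRounds = 3L, seed = 4L)
  expect_true(all(h2[1, ] != h2[2, ]))
  expect_identical(lshHash(v, 8L, 3L, seed = 9L), lshHash(v, 8L, 3L, seed = 9L))
  expect_false(identical(lshHash(v, 8L, 3L, seed = 9L),
                         lshHash(v, 8L, 3L, seed = 10L)))
})

test_that("hash buckets are near-uniform on isotropic Gaussian vectors", {
  withr::with_seed(2022L, X <- matrix(rnorm(1000 * 32), 1000, 32))
  h <- lshHash(X, nBuckets = 64L, nRounds = 1L, seed = 1L)
  tab <- table(factor(h[, 1], levels = 1:64))
  p <- suppressWarnings(chisq.test(tab)$p.value)
  expect_gt(p, 0.01)
})

test_that("single-bucket LSH attention equals full attention", {
  for (s in 1:10) {
    withr::with_seed(s, {
      n <- sample(2:64, 1); dk <- sample(2:32, 1)
      Q <- matrix(rnorm(n * dk), n, dk)
      V <- matrix(rnorm(n * dk), n, dk)
    })
    K <- Q / pmax(sqrt(rowSums(Q^2)), 1e-12)
    expect_lt(max(abs(lshAttention(Q, V, nBuckets = 1L) -
                      fullAttention(Q, K, V))), 1e-5)
  }
})

test_that("LSH attention with a fixed assignment matches the restricted softmax", {
  withr::with_seed(8L, {
    Q <- matrix(rnorm(3 * 2), 3, 2)
    V <- matrix(rnorm(3 * 2), 3, 2)
  })
  K <- Q / sqrt(rowSums(Q^2))
  asg <- matrix(c(1L, 1L, 2L), 3, 1)  # buckets {1,2} and {3}
  out <- lshAttention(Q, V, assignment = asg)
  brute <- matrix(0, 3, 2)
  for (i in 1:3) {
    P <- which(asg[, 1] == asg[i, 1])
    s <- as.numeric(K[P, , drop = FALSE] %*% Q[i, ]) / sqrt(2)
    w <- exp(s - max(s)); w <- w / sum(w)
    brute[i, ] <- as.numeric(t(V[P, , drop = FALSE]) %*% w)
  }
  expect_equal(out, brute, tolerance = 1e-6)
  expect_error(lshAttention(Q, V, assignment = matrix(1L, 2, 1)), "length")
})

test_that("softmax rows over candidate sets are convex weights", {
  withr::with_seed(3L, {
    Q <- matrix(rnorm(20 * 4), 20, 4)
    V <- matrix(rnorm(20 * 4), 20, 4)
  })
  out <- lshAttention(Q, V, nBuckets = 4L, nRounds = 2L, seed = 5L)
  asg <- lshHash(Q, 4L, 2L, seed = 5L)
  M <- screformer:::bucketMask(asg, 4L, chunked = TRUE)
  for (i in 1:20) {
    P <- which(M[i, ])
    expect_true(all(out[i, ] <= apply(V[P, , drop = FALSE], 2, max) + 1e-10))
    expect_true(all(out[i, ] >= apply(V[P, , drop = FALSE], 2, min) - 1e-10))
  }
})

test_that("clustered inputs make LSH attention track full attention better than random buckets", {
  wins <- 0L
  for (s in 1:40) {
    withr::with_seed(s, {
      centers <- matrix(rnorm(4 * 8, sd = 4), 4, 8)
      idx <- rep(1:4, each = 8)
      Q <- centers[idx, ] + matrix(rnorm(32 * 8, sd = 0.05), 32, 8)
      V <- matrix(rnorm(32 * 8), 32, 8)
      randAsg <- matrix(sample(1:8, 32 * 4, replace = TRUE), 32, 4)
    })
    K <- Q / pmax(sqrt(rowSums(Q^2)), 1e-12)
    ref <- fullAttention(Q, K, V)
    lsh <- lshAttention(Q, V, nBuckets = 8L, nRounds = 4L, seed = s)
    rnd <- lshAttention(Q, V, assignment = randAsg)
    if (max(abs(lsh - ref)) < max(abs(rnd - ref))) wins <- wins + 1L
  }
  expect_gte(wins, 0.95 * 40)
})

test_that("reversible coupling is exactly invertible and identity for zero maps", {
  zero <- function(x) x * 0
  x1 <- matrix(1:6 / 7, 2, 3); x2 <- matrix(6:1 / 7, 2, 3)
  fw <- reversibleForward(x1, x2, zero, zero)
  expect_identical(fw$y1, x1); expect_identical(fw$y2, x2)
  for (s in 1:25) {
    withr::with_seed(s, {
      n <- sample(2:8, 1); d <- sample(2:8, 1)
      W1 <- matrix(rnorm(d * d), d, d); W2 <- matrix(rnorm(d * d), d, d)
      x1 <- matrix(rnorm(n * d), n, d); x2 <- matrix(rnorm(n * d), n, d)
    })
    F <- function(x) tanh(x %*% W1)
    G <- function(x) tanh(x %*% W2)
    fw <- reversibleForward(x1, x2, F, G)
    iv <- reversibleInverse(fw$y1, fw$y2, F, G)
    expect_lt(max(abs(iv$x1 - x1)), 1e-4)
    expect_lt(max(abs(iv$x2 - x2)), 1e-4)
  }
  expect_error(reversibleForward(matrix(0, 2, 2), matrix(0, 3, 2),
                                 zero, zero), "shape")
})

test_that("recompute-on-backward gradients equal the stored-activation baseline", {
  cfg <- tinyConfig(seqLen = 14L, nBuckets = 2L, nHashRounds = 2L)
  model <- initReformer(cfg, sprintf("g%02d", 1:14), seed = 5L)
  withr::with_seed(6L, bins <- sample(0:4, 14, replace = TRUE))
  nz <- which(bins > 0)
  maskPos <- nz[1:2]; targets <- bins[maskPos]
  bm <- bins; bm[maskPos[1]] <- 5L
  gRec <- screformer:::mlmCellGrad(model@params, cfg, bm, maskPos, targets,
                                   seed = 2L, storeActivations = FALSE)
  gSto <- screformer:::mlmCellGrad(model@params, cfg, bm, maskPos, targets,
                                   seed = 2L, storeActivations = TRUE)
  expect_equal(gRec$loss, gSto$loss)
  rel <- function(a, b) max(abs(a - b)) / max(1e-12, max(abs(b)))
  expect_lt(rel(gRec$grads$geneEmb, gSto$grads$geneEmb), 1e-4)
  for (l in 1:2) for (nm in names(gRec$grads$layers[[l]]))
    expect_lt(rel(gRec$grads$layers[[l]][[nm]],
                  gSto$grads$layers[[l]][[nm]]), 1e-4)
})

test_that("token embedding is the sum of gene, bin and positional terms", {
  cfg <- tinyConfig(seqLen = 4L, nBins = 3L, dModel = 6L, nLayers = 0L,
                    nHeads = 2L, dFf = 8L)
  model <- initReformer(cfg, paste0("g", 1:4), seed = 2L)
  bins <- c(0L, 2L, 1L, 3L)  # 3 = MASK for nBins = 3
  pe <- sinusoidalEncoding(4L, 6L)
  # zero learned embeddings -> output is exactly the positional encoding
  m0 <- model
  m0@params$geneEmb[] <- 0; m0@params$binEmb[] <- 0
  expect_equal(embedTokens(m0, bins), pe, ignore_attr = TRUE)
  # linearity: doubling both tables doubles (output - positional term)
  m2 <- model
  m2@params$geneEmb <- 2 * model@params$geneEmb
  m2@params$binEmb <- 2 * model@params$binEmb
  expect_equal(embedTokens(m2, bins) - pe,
               2 * (embedTokens(model, bins) - pe))
  # independent three-matrix sum
  expected <- model@params$geneEmb + model@params$binEmb[bins + 1L, ] + pe
  expect_equal(embedTokens(model, bins), expected, ignore_attr = TRUE)
  expect_error(embedTokens(model, c(0L, 9L, 0L, 0L)), "range")
})

test_that("the encoder collapses to the embedding for an empty stack and keeps shape", {
  cfg0 <- tinyConfig(seqLen = 5L, nLayers = 0L, dModel = 6L)
  m0 <- initReformer(cfg0, paste0("g", 1:5), seed = 1L)
  bins <- c(0L, 1L, 2L, 3L, 4L)
  expect_equal(encodeCell(m0, bins), embedTokens(m0, bins), ignore_attr = TRUE)
  cfg <- tinyConfig(seqLen = 16L, dModel = 20L, nHeads = 2L, nBuckets = 2L)
  m <- initReformer(cfg, sprintf("g%02d", 1:16), seed = 1L)
  withr::with_seed(2L, b16 <- sample(0:4, 16, replace = TRUE))
  expect_equal(dim(encodeCell(m, b16)), c(16L, 20L))
})

test_that("a single-bucket encoder equals a full-attention reference encoder", {
  cfgLsh <- tinyConfig(seqLen = 16L, dModel = 20L, nHeads = 2L,
                       nBuckets = 1L, nHashRounds = 1L)
  cfgFull <- tinyConfig(seqLen = 16L, dModel = 20L, nHeads = 2L,
                        nBuckets = 1L, attention = "full")
  m <- initReformer(cfgLsh, sprintf("g%02d", 1:16), seed = 7L)
  mFull <- m; mFull@config <- cfgFull
  withr::with_seed(3L, bins <- sample(0:4, 16, replace = TRUE))
  expect_lt(max(abs(encodeCell(m, bins) - encodeCell(mFull, bins))), 1e-5)
})

test_that("hash determinism makes encoding reproducible across runs", {
  cfg <- tinyConfig(seqLen = 24L, dModel = 8L, nBuckets = 4L)
  m <- initReformer(cfg, sprintf("g%02d", 1:24), seed = 3L)
  withr::with_seed(4L, bins <- sample(0:4, 24, replace = TRUE))
  expect_identical(encodeCell(m, bins, seed = 11L),
                   encodeCell(m, bins, seed = 11L))
})
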