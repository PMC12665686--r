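test_that("the classification head softmax behaves canonically", {
  cfg <- tinyConfig(seqLen = 6L, dModel = 8L, nHeads = 2L)
  m <- initReformer(cfg, paste0("g", 1:6), seed = 1L, nClasses = 4L)
  H <- matrix(0.3, 6, 8)
  # equal logits -> uniform probabilities
  m0 <- m
  m0@params$clsHead$W3[] <- 0
  m0@params$clsHead$b3[] <- 1.5
  p <- screformer:::clsHeadForward(H, m0@params, cfg)$probs
  expect_equal(p, rep(0.25, 4))
  # shifting all logits leaves probabilities unchanged
  m1 <- m0; m1@params$clsHead$b3 <- m0@params$clsHead$b3 + 7
  expect_equal(screformer:::clsHeadForward(H, m1@params, cfg)$probs, p)
  # layer-by-layer oracle: conv + pool + 3 dense layers by hand
  hp <- m@params$clsHead
  lrelu <- function(x) pmax(x, 0) + 0.01 * pmin(x, 0)
  Zc <- lrelu(H %*% hp$Wc + matrix(hp$bc, 6, length(hp$bc), byrow = TRUE))
  pooled <- c(colMeans(Zc), apply(Zc, 2, max))
  h1 <- lrelu(as.numeric(pooled %*% hp$W1) + hp$b1)
  h2 <- lrelu(as.numeric(h1 %*% hp$W2) + hp$b2)
  lg <- as.numeric(h2 %*% hp$W3) + hp$b3
  ex <- exp(lg - max(lg)); ex <- ex / sum(ex)
  expect_equal(screformer:::clsHeadForward(H, m@params, cfg)$probs, ex,
               tolerance = 1e-6)
})

test_that("the classification loss has its closed forms", {
  expect_equal(clsLoss(matrix(c(0, 1, 0), 1), 2L), 0)
  expect_equal(clsLoss(matrix(1 / 9, 1, 9), 5L), log(9))
  Q <- rbind(c(0.6, 0.4), c(0.25, 0.75), c(0.5, 0.5), c(0.9, 0.1))
  z <- c(1L, 2L, 1L, 1L)
  expect_equal(clsLoss(Q, z),
               -(log(0.6) + log(0.75) + log(0.5) + log(0.9)))
  # uniform classifier: exactly m * ln C
  expect_equal(clsLoss(matrix(0.2, 7, 5), rep(3L, 7)), 7 * log(5))
})

test_that("prediction takes the argmax with low-index tie-breaking", {
  fx <- smallFixture()
  model <- smallModel()$model
  probs <- rbind(c(0.2, 0.5, 0.3, 0))
  expect_equal(which.max(probs), 2L)  # documented 0-based class 1
  # explicit tie rule through the exported surface
  cfg <- tinyConfig(seqLen = 4L, dModel = 8L, nHeads = 2L)
  m <- initReformer(cfg, paste0("g", 1:4), seed = 2L, nClasses = 2L)
  m@classes <- c("A", "B")
  m@params$clsHead$W3[] <- 0; m@params$clsHead$b3[] <- 0  # exact tie
  pred <- predictCells(m, matrix(c(0L, 1L, 2L, 0L), 1))
  expect_equal(as.character(pred$labels), "A")
  # sequence-length mismatch is refused
  expect_error(predictCells(model, matrix(0L, 1, 3)), "genes")
})

test_that("prediction is invariant to batch composition", {
  run <- smallModel()
  fx <- smallFixture()
  tok <- subsetCells(fx$tokens, run$testIds[1:6])
  all_ <- predictCells(run$model, tok)
  one <- t(vapply(1:6, function(i)
    predictCells(run$model, subsetCells(tok, i))$probs[1, ], numeric(4)))
  expect_equal(unname(all_$probs), unname(one), tolerance = 1e-12)
})

test_that("fine-tuning with zero learning rate stops after patience", {
  fx <- smallFixture()
  cfg <- smallConfig()
  idx <- 1:60
  m <- initReformer(cfg, geneIds(fx$tokens), scheme = fx$scheme, seed = 4L)
  fit <- finetuneReformer(m, subsetCells(fx$tokens, idx),
                          fx$labels[idx, "level1"],
                          subsetCells(fx$tokens, 61:80),
                          fx$labels[61:80, "level1"],
                          epochs = 5L, batchSize = 16L, lr = 0, seed = 4L)
  h <- trainingHistory(fit)
  expect_lte(nrow(h), 2L)  # patience-1 stop once accuracy stalls
  expect_equal(length(unique(h$valAccuracy)), 1L)
})

test_that("a validation class missing from training is refused", {
  fx <- smallFixture()
  cfg <- smallConfig()
  m <- initReformer(cfg, geneIds(fx$tokens), scheme = fx$scheme, seed = 4L)
  tr <- which(fx$labels$level1 == "type1")[1:10]
  va <- which(fx$labels$level1 == "type2")[1:5]
  expect_error(finetuneReformer(m, subsetCells(fx$tokens, tr),
                                fx$labels[tr, "level1"],
                                subsetCells(fx$tokens, va),
                                fx$labels[va, "level1"],
                                epochs = 1L, seed = 1L),
               "absent from training")
})

test_that("fine-tuning recovers the planted types above the majority baseline", {
  run <- smallModel()
  fx <- smallFixture()
  majority <- max(table(fx$labels$level1)) / nrow(fx$labels)
  expect_gt(run$accuracy, majority)
  h <- trainingHistory(run$model)
  # early stopping never returns a worse checkpoint than seen before
  expect_equal(max(h$valAccuracy), h$valAccuracy[which.max(h$valAccuracy)])
})

test_that("cross-validation folds are disjoint, exhaustive and seeded", {
  fx <- smallFixture()
  cls <- fx$labels$level1
  m <- initReformer(smallConfig(), geneIds(fx$tokens), scheme = fx$scheme,
                    seed = 1L)
  idx <- 1:40
  cv <- crossValidate(m, subsetCells(fx$tokens, idx), cls[idx], k = 2L,
                      seed = 9L, epochs = 1L, batchSize = 16L, lr = 1e-3)
  expect_setequal(unique(cv$folds), 1:2)
  expect_length(cv$folds, 40L)
  cv2 <- crossValidate(m, subsetCells(fx$tokens, idx), cls[idx], k = 2L,
                       seed = 9L, epochs = 1L, batchSize = 16L, lr = 1e-3)
  expect_identical(cv$folds, cv2$folds)
  expect_equal(dim(cv$summary), c(2L, 3L))
  expect_error(crossValidate(m, subsetCells(fx$tokens, 1:3), cls[1:3],
                             k = 5L, seed = 1L), "exceeds")
})

test_that("k = 2 on 10 cells gives two folds of five, each cell tested once", {
  fx <- smallFixture()
  cls <- rep(c("a", "b"), 5)
  m <- initReformer(smallConfig(), geneIds(fx$tokens), scheme = fx$scheme,
                    seed = 1L)
  cv <- crossValidate(m, subsetCells(fx$tokens, 1:10), cls, k = 2L,
                      seed = 3L, epochs = 1L, batchSize = 4L, lr = 1e-3)
  expect_equal(unname(table(cv$folds)), array(c(5L, 5L)), ignore_attr = TRUE)
  # per-fold confusion totals account for every cell exactly once
  expect_equal(sum(vapply(cv$reports, function(r) sum(r@confusion),
                          numeric(1))), 10)
})
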