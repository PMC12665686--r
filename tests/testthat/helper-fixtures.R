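# Shared fixtures. Expensive objects (trained models) are built lazily and
# cached for the whole test run so several test files can share them.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

tinyConfig <- function(seqLen, nBins = 5L, ...) {
  defaults <- list(seqLen = seqLen, nBins = nBins, dModel = 8L, nLayers = 2L,
                   nHeads = 2L, nBuckets = 2L, nHashRounds = 2L, dropout = 0,
                   dFf = 12L, convChannels = 6L, hiddenSizes = c(8L, 6L))
  args <- utils::modifyList(defaults, list(...))
  do.call(reformerConfig, args)
}

randomSCE <- function(nGenes = 6L, nCells = 4L, seed = 1L, maxCount = 9L) {
  withr::with_seed(seed, {
    m <- matrix(rpois(nGenes * nCells, 2), nGenes, nCells)
    m[sample(length(m), length(m) %/% 3)] <- 0
    dimnames(m) <- list(sprintf("G%03d", seq_len(nGenes)),
                        sprintf("c%03d", seq_len(nCells)))
    SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = methods::as(Matrix::Matrix(m, sparse = TRUE),
                                         "CsparseMatrix")))
  })
}

# the reference planted-marker fixture: 2000 cells x 300 genes, 5 types
defaultFixture <- function() {
  cached("defaultFixture", {
    sim <- simulateCells(seed = 2022L)
    sce <- filterGenes(sim$sce, sim$embeddings)
    scheme <- fitBins(sce, nBins = 7L)
    tokens <- tokenizeCells(sce, scheme)
    c(sim, list(tokens = tokens, scheme = scheme))
  })
}

# encoder configuration for the fixture-scale experiments
fixtureConfig <- function() {
  tok <- defaultFixture()$tokens
  reformerConfig(seqLen = ncol(tokenBins(tok)), nBins = 7L, dModel = 32L,
                 nLayers = 2L, nHeads = 2L, nBuckets = 8L, nHashRounds = 1L,
                 dropout = 0, dFf = 64L, convChannels = 32L,
                 hiddenSizes = c(64L, 64L))
}

# one shared pre-trained encoder on the default fixture (used by the
# learning, classification and attribution checks)
fixturePretrained <- function() {
  cached("fixturePretrained", {
    fx <- defaultFixture()
    pretrainReformer(fx$tokens, fixtureConfig(), embeddings = fx$embeddings,
                     epochs = 3L, batchSize = 32L, lr = 1e-3, seed = 2022L)
  })
}

# fine-tuned classifier on the default fixture (6:2:2 split)
fixtureFinetuned <- function() {
  cached("fixtureFinetuned", {
    fx <- defaultFixture()
    split <- splitCells(fx$labels, c(0.6, 0.2, 0.2), seed = 2022L)
    tr <- splitIds(split, "train"); va <- splitIds(split, "val")
    te <- splitIds(split, "test")
    fit <- finetuneReformer(fixturePretrained(),
      subsetCells(fx$tokens, tr), fx$labels[tr, "level1"],
      subsetCells(fx$tokens, va), fx$labels[va, "level1"],
      epochs = 10L, batchSize = 4L, lr = 3e-3, patience = 10L,
      seed = 2022L)
    pred <- predictCells(fit, subsetCells(fx$tokens, te))
    acc <- mean(as.character(pred$labels) == fx$labels[te, "level1"])
    list(model = fit, accuracy = acc, pred = pred, testIds = te,
         split = split)
  })
}

# a reduced fixture for the ablation grid and attribution checks
smallFixture <- function() {
  cached("smallFixture", {
    sim <- simulateCells(nCells = 500L, nGenes = 120L, nTypes = 4L,
                         markersPerType = 10L, dEmbed = 16L, seed = 2022L)
    sce <- filterGenes(sim$sce, sim$embeddings)
    scheme <- fitBins(sce, nBins = 7L)
    tokens <- tokenizeCells(sce, scheme)
    c(sim, list(tokens = tokens, scheme = scheme))
  })
}

smallConfig <- function() {
  tok <- smallFixture()$tokens
  reformerConfig(seqLen = ncol(tokenBins(tok)), nBins = 7L, dModel = 16L,
                 nLayers = 2L, nHeads = 2L, nBuckets = 4L, nHashRounds = 1L,
                 dropout = 0, dFf = 32L, convChannels = 16L,
                 hiddenSizes = c(32L, 32L))
}

# pretrain (optional) + finetune on the small fixture; returns the
# fine-tuned model and its test-set accuracy
smallRun <- function(seed, usePretraining = TRUE, useEmbeddings = TRUE,
                     pretrainEpochs = 2L, finetuneEpochs = 10L) {
  fx <- smallFixture()
  cfg <- smallConfig()
  split <- splitCells(fx$labels, c(0.6, 0.2, 0.2), seed = seed)
  tr <- splitIds(split, "train"); va <- splitIds(split, "val")
  te <- splitIds(split, "test")
  emb <- if (useEmbeddings) fx$embeddings else NULL
  base <- if (usePretraining) {
    pretrainReformer(subsetCells(fx$tokens, c(tr, va)), cfg,
                     embeddings = emb, epochs = pretrainEpochs,
                     batchSize = 32L, lr = 1e-3, seed = seed)
  } else {
    m <- initReformer(cfg, geneIds(fx$tokens), embeddings = emb,
                      scheme = fx$scheme, seed = seed)
    m
  }
  fit <- finetuneReformer(base,
    subsetCells(fx$tokens, tr), fx$labels[tr, "level1"],
    subsetCells(fx$tokens, va), fx$labels[va, "level1"],
    epochs = finetuneEpochs, batchSize = 4L, lr = 3e-3,
    patience = finetuneEpochs, seed = seed)
  pred <- predictCells(fit, subsetCells(fx$tokens, te))
  acc <- mean(as.character(pred$labels) == fx$labels[te, "level1"])
  list(model = fit, accuracy = acc, testIds = te, pred = pred)
}

# full model trained on the small fixture (shared by attribution tests)
smallModel <- function() {
  cached("smallModel", smallRun(2022L))
}

# exact Shapley by subset enumeration (test oracle, <= ~12 features)
exactShapley <- function(f, x, background) {
  L <- length(x)
  phi <- numeric(L)
  vOf <- function(Smask) {
    hyb <- background
    if (any(Smask)) hyb[, Smask] <- matrix(x[Smask], nrow(background),
                                           sum(Smask), byrow = TRUE)
    mean(f(hyb))
  }
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), L))
  vals <- apply(as.matrix(subsets), 1L, vOf)
  sizes <- rowSums(as.matrix(subsets))
  key <- function(mask) sum(2^(which(mask) - 1)) + 1
  for (g in seq_len(L)) {
    others <- which(!as.matrix(subsets)[, g])
    for (ri in others) {
      mask <- as.logical(as.matrix(subsets)[ri, ])
      s <- sizes[ri]
      w <- factorial(s) * factorial(L - s - 1) / factorial(L)
      maskG <- mask; maskG[g] <- TRUE
      phi[g] <- phi[g] + w * (vals[key(maskG)] - vals[key(mask)])
    }
  }
  phi
}
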