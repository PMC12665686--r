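test_that("gene filtering intersects expressed genes with the vocabulary", {
  m <- matrix(0, 5, 3, dimnames = list(paste0("g", 1:5), paste0("c", 1:3)))
  m["g1", 1] <- 2; m["g2", 2] <- 1; m["g5", 3] <- 4  # g3, g4 silent
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(m, sparse = TRUE),
                                       "CsparseMatrix")))
  vocab <- methods::new("GeneEmbeddings", ids = c("g1", "g2", "g3", "g4"),
                        vectors = matrix(0.1, 4, 2))  # g5 out of vocab
  out <- filterGenes(sce, vocab)
  expect_identical(rownames(out), c("g1", "g2"))
  rep <- S4Vectors::metadata(out)$geneFilter
  expect_equal(rep$nRetained, 2L)
  # idempotent
  expect_identical(rownames(filterGenes(out, vocab)), rownames(out))
  # identity case: full vocabulary, no silent genes
  m2 <- m; m2[m2 == 0] <- 1
  sce2 <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(m2, sparse = TRUE)))
  vocab2 <- methods::new("GeneEmbeddings", ids = paste0("g", 1:5),
                         vectors = matrix(0.1, 5, 2))
  expect_identical(rownames(filterGenes(sce2, vocab2)), rownames(sce2))
  # nothing retained -> instructive error
  vocabNone <- methods::new("GeneEmbeddings", ids = "zzz",
                            vectors = matrix(0.1, 1, 2))
  expect_error(filterGenes(sce, vocabNone), "vocabulary")
})

test_that("filtering matches a brute-force set computation on a planted fixture", {
  sim <- simulateCells(nCells = 60L, nGenes = 500L, nTypes = 2L,
                       markersPerType = 5L, dropoutRate = 0.2,
                       vocabDropFrac = 0.2, dEmbed = 8L, seed = 5L)
  # silence 50 genes outright
  m <- SummarizedExperiment::assay(sim$sce, "counts")
  m[451:500, ] <- 0
  SummarizedExperiment::assay(sim$sce, "counts") <- m
  expressed <- rownames(sim$sce)[Matrix::rowSums(m != 0) > 0]
  expected <- intersect(rownames(sim$sce),
                        intersect(expressed, embeddingIds(sim$embeddings)))
  out <- filterGenes(sim$sce, sim$embeddings)
  expect_identical(rownames(out), expected)
})

test_that("bin edges follow empirical quantiles of the nonzero values", {
  withr::with_seed(3L, {
    vals <- exp(rnorm(4000, sd = 1))
    m <- matrix(vals, 40, 100)
  })
  scheme <- fitBins(m, nBins = 7L, transform = "log1p")
  expect_s4_class(scheme, "BinningScheme")
  expect_length(scheme@edges, 6L)
  expect_equal(scheme@edges,
               unname(quantile(log1p(vals), probs = (1:6) / 6)))
  # occupancy of bins 1..6 within 2x of the uniform share
  ids <- binValues(as.numeric(m), scheme)
  occ <- table(factor(ids, levels = 1:6))
  expect_true(all(occ <= 2 * length(vals) / 6))
  expect_true(all(occ >= length(vals) / 6 / 2))
})

test_that("degenerate and boundary binning cases behave as documented", {
  m <- matrix(7, 3, 3)
  scheme <- fitBins(m, nBins = 5L)
  expect_equal(unique(binValues(rep(7, 9), scheme)), 1L)  # one shared bin
  expect_error(fitBins(matrix(0, 2, 2), nBins = 4L), "zero")
  # monotone over 0..100
  s2 <- fitBins(matrix(0:100, 1), nBins = 5L)
  b <- binValues(as.numeric(0:100), s2)
  expect_true(all(diff(b) >= 0))
  expect_equal(b[1], 0L)          # zero -> reserved bin 0
  expect_equal(b[101], 4L)        # training maximum -> top bin
  expect_equal(binValues(1e6, s2), 4L)  # beyond the maximum stays clamped
  expect_error(binValues(c(1, -2), s2), "negative")
})

test_that("tokenization matches a linear edge-scan oracle on random rows", {
  sce <- randomSCE(nGenes = 15L, nCells = 20L, seed = 9L)
  scheme <- fitBins(sce, nBins = 6L)
  tokens <- tokenizeCells(sce, scheme)
  m <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
  oracle <- function(v) {
    if (v == 0) return(0L)
    tv <- log1p(v)
    min(1L + sum(scheme@edges < tv), 5L)
  }
  for (i in seq_len(ncol(m))) {
    expect_equal(tokenBins(tokens)[i, ],
                 vapply(m[, i], oracle, integer(1)),
                 ignore_attr = TRUE)
  }
  # all-zero row maps to all bin 0
  expect_equal(unique(binValues(rep(0, 5), scheme)), 0L)
})

test_that("binning schemes serialize to JSON and back", {
  sce <- randomSCE(seed = 2L)
  scheme <- fitBins(sce, nBins = 7L)
  f <- withr::local_tempfile(fileext = ".json")
  writeBinningScheme(scheme, f)
  back <- readBinningScheme(f)
  expect_equal(back@edges, scheme@edges)
  expect_identical(back@nBins, scheme@nBins)
  expect_identical(back@transform, scheme@transform)
})

test_that("per-gene binning uses each gene's own quantile edges", {
  m <- rbind(g1 = c(0, 1, 2, 3, 4), g2 = c(0, 10, 20, 30, 40))
  colnames(m) <- paste0("c", 1:5)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(m, sparse = TRUE)))
  scheme <- fitBins(sce, nBins = 4L, transform = "identity", perGene = TRUE)
  tokens <- tokenizeCells(sce, scheme)
  # same relative position in each gene's distribution -> same bin
  expect_equal(tokenBins(tokens)[, "g1"], tokenBins(tokens)[, "g2"],
               ignore_attr = TRUE)
})
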