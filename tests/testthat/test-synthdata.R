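test_that("simulated datasets are deterministic integer-count objects", {
  a <- simulateCells(nCells = 50L, nGenes = 40L, nTypes = 2L,
                     markersPerType = 4L, dEmbed = 8L, seed = 7L)
  b <- simulateCells(nCells = 50L, nGenes = 40L, nTypes = 2L,
                     markersPerType = 4L, dEmbed = 8L, seed = 7L)
  ma <- as.matrix(SummarizedExperiment::assay(a$sce, "counts"))
  expect_identical(ma, as.matrix(SummarizedExperiment::assay(b$sce, "counts")))
  expect_identical(a$labels, b$labels)
  expect_identical(embeddingVectors(a$embeddings),
                   embeddingVectors(b$embeddings))
  expect_true(all(ma >= 0) && all(ma == round(ma)))
  # labels fill all four levels and marker sets are disjoint
  expect_true(all(as.matrix(as.data.frame(a$labels)) != ""))
  expect_equal(anyDuplicated(unlist(a$truth$markers)), 0L)
  expect_error(simulateCells(nGenes = 10L, nTypes = 4L, markersPerType = 5L),
               "infeasible")
})

test_that("marker genes are overexpressed in their own type", {
  sim <- simulateCells(nCells = 2000L, nGenes = 100L, nTypes = 4L,
                       markersPerType = 8L, foldChange = 8, dropoutRate = 0,
                       dEmbed = 8L, seed = 3L)
  m <- as.matrix(SummarizedExperiment::assay(sim$sce, "counts"))
  hits <- 0L; tot <- 0L
  for (t in names(sim$truth$markers)) {
    own <- sim$truth$type == t
    for (g in sim$truth$markers[[t]]) {
      tot <- tot + 1L
      if (mean(m[g, own]) > mean(m[g, !own])) hits <- hits + 1L
    }
  }
  expect_gte(hits / tot, 0.95)
})

test_that("the null-effect limit erases the marker signal", {
  sim <- simulateCells(nCells = 400L, nGenes = 60L, nTypes = 2L,
                       markersPerType = 25L, foldChange = 1 + 1e-12,
                       dropoutRate = 0, dEmbed = 8L, seed = 11L)
  m <- as.matrix(SummarizedExperiment::assay(sim$sce, "counts"))
  own <- sim$truth$type == "type1"
  pvals <- vapply(sim$truth$markers$type1, function(g)
    suppressWarnings(wilcox.test(m[g, own], m[g, !own])$p.value), numeric(1))
  expect_lte(sum(pvals < 0.01), 0.2 * length(pvals))
})

test_that("the zero fraction grows with the dropout rate", {
  zf <- vapply(c(0, 0.3, 0.6), function(d) {
    s <- simulateCells(nCells = 150L, nGenes = 50L, nTypes = 2L,
                       markersPerType = 5L, dropoutRate = d, dEmbed = 8L,
                       seed = 5L)
    m <- SummarizedExperiment::assay(s$sce, "counts")
    mean(as.matrix(m) == 0)
  }, numeric(1))
  expect_true(all(diff(zf) > 0))
})

test_that("a nearest-centroid classifier on the truth markers succeeds", {
  sim <- simulateCells(nCells = 600L, nGenes = 120L, nTypes = 4L,
                       markersPerType = 10L, foldChange = 8,
                       dropoutRate = 0.1, dEmbed = 8L, seed = 13L)
  m <- as.matrix(SummarizedExperiment::assay(sim$sce, "counts"))
  score <- vapply(names(sim$truth$markers), function(t)
    colMeans(m[sim$truth$markers[[t]], ]), numeric(ncol(m)))
  pred <- colnames(score)[max.col(score)]
  expect_gt(mean(pred == unname(sim$truth$type)), 0.9)
})

test_that("generated embeddings separate marker modules", {
  sim <- simulateCells(nCells = 30L, nGenes = 80L, nTypes = 2L,
                       markersPerType = 10L, dEmbed = 50L, withinSim = 0.7,
                       seed = 21L)
  V <- embeddingVectors(sim$embeddings)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  pairMean <- function(ids1, ids2) {
    v <- c()
    for (g1 in ids1) for (g2 in ids2)
      if (g1 != g2) v <- c(v, cosine(V[g1, ], V[g2, ]))
    mean(v)
  }
  m1 <- sim$truth$markers$type1; m2 <- sim$truth$markers$type2
  within1 <- pairMean(m1, m1)
  between <- pairMean(m1, m2)
  expect_gt(within1, 0.5)
  expect_lt(abs(between), 0.2)
  expect_gt(within1, abs(between))
  # near-unit similarity in the withinSim -> 1 limit
  hi <- simulateGeneEmbeddings(sim$truth, dEmbed = 50L, withinSim = 0.999,
                               geneIds = embeddingIds(sim$embeddings),
                               seed = 2L)
  Vh <- embeddingVectors(hi)
  cosHi <- cosine(Vh[m1[1], ], Vh[m1[2], ])
  expect_gt(cosHi, 0.95)
  expect_error(simulateGeneEmbeddings(sim$truth, dEmbed = 1L,
                                      withinSim = 0.7), "too small")
  # deterministic
  expect_identical(embeddingVectors(simulateGeneEmbeddings(sim$truth, 20L,
                                                           0.7, seed = 8L)),
                   embeddingVectors(simulateGeneEmbeddings(sim$truth, 20L,
                                                           0.7, seed = 8L)))
})

test_that("omitted vocabulary fractions propagate to the embedding table", {
  sim <- simulateCells(nCells = 30L, nGenes = 100L, nTypes = 2L,
                       markersPerType = 5L, vocabDropFrac = 0.25,
                       dEmbed = 8L, seed = 9L)
  expect_equal(length(embeddingIds(sim$embeddings)), 75L)
})
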