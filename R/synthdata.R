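#' Simulate an scRNA-seq dataset with planted cell-type structure
#'
#' Gamma-Poisson (negative binomial) counts with a single dispersion
#' parameter — the standard overdispersion model for UMI counts. Each of
#' the `nTypes` level-1 cell types owns a disjoint module of
#' `markersPerType` marker genes whose mean is multiplied by `foldChange`
#' in cells of that type; technical dropout independently zeroes entries
#' at rate `dropoutRate`. Cells draw their type from `typeProportions`. A
#' 4-level label tree is built by nesting each level-1 type into generated
#' sub-labels with downward propagation where a branch ends early, and a
#' matching Gene2vec-style embedding table is generated so co-module genes
#' are mutually similar. Fully determined by the seed.
#'
#' @param nCells,nGenes matrix dimensions.
#' @param nTypes number of level-1 cell types (>= 2).
#' @param markersPerType markers per type (disjoint modules;
#'   `nTypes * markersPerType <= nGenes`).
#' @param foldChange multiplicative marker effect (> 1).
#' @param baseMean NB mean of a background gene (> 0).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param dropoutRate independent zeroing probability in [0, 1).
#' @param typeProportions simplex vector of type frequencies (default
#'   mildly imbalanced).
#' @param dEmbed embedding dimension of the generated table.
#' @param withinSim target mean pairwise cosine similarity within a
#'   marker module.
#' @param vocabDropFrac fraction of gene ids deliberately omitted from
#'   the embedding table (to exercise vocabulary filtering; default 0).
#' @param seed integer seed.
#' @return list with `sce` (a `SingleCellExperiment`; `colData` holds
#'   `level1..level4`), `labels` (label DataFrame), `truth` (list with
#'   per-type marker gene ids and the generative parameters) and
#'   `embeddings` (a [GeneEmbeddings-class]).
#' @export
simulateCells <- function(nCells = 2000L, nGenes = 300L, nTypes = 5L,
                          markersPerType = 10L, foldChange = 6,
                          baseMean = 2, dispersion = 0.5,
                          dropoutRate = 0.3, typeProportions = NULL,
                          dEmbed = 32L, withinSim = 0.7,
                          vocabDropFrac = 0, seed = 2022L) {
  if (nTypes * markersPerType > nGenes)
    stop("infeasible: nTypes * markersPerType > nGenes", call. = FALSE)
  if (nTypes < 2L) stop("need at least 2 types", call. = FALSE)
  if (foldChange <= 0 || baseMean <= 0 || dispersion <= 0)
    stop("foldChange, baseMean, dispersion must be positive", call. = FALSE)
  if (dropoutRate < 0 || dropoutRate >= 1)
    stop("dropoutRate must be in [0, 1)", call. = FALSE)
  if (is.null(typeProportions))
    typeProportions <- {
      w <- seq(nTypes, 1); w / sum(w)
    }
  if (length(typeProportions) != nTypes ||
      abs(sum(typeProportions) - 1) > 1e-8)
    stop("typeProportions must be a length-nTypes simplex vector", call. = FALSE)

  geneIdsV <- sprintf("G%04d", seq_len(nGenes))
  cellIdsV <- sprintf("cell%05d", seq_len(nCells))
  types <- paste0("type", seq_len(nTypes))
  markers <- split(geneIdsV[seq_len(nTypes * markersPerType)],
                   rep(types, each = markersPerType))[types]

  res <- withSeed(seed, {
    z <- sample(types, nCells, replace = TRUE, prob = typeProportions)
    mu <- matrix(baseMean, nGenes, nCells, dimnames = list(geneIdsV, cellIdsV))
    for (t in types) {
      gi <- match(markers[[t]], geneIdsV)
      mu[gi, z == t] <- baseMean * foldChange
    }
    size <- 1 / dispersion
    counts <- matrix(stats::rnbinom(nGenes * nCells, mu = mu, size = size),
                     nGenes, nCells, dimnames = dimnames(mu))
    if (dropoutRate > 0) {
      drop <- matrix(stats::runif(nGenes * nCells) < dropoutRate,
                     nGenes, nCells)
      counts[drop] <- 0L
    }
    # nested 4-level tree: every type splits into two level-2 subsets;
    # the first subset carries two level-3 children, of which the first
    # gains a level-4 child — the rest end early and propagate downward
    lv <- matrix("", nCells, 4L, dimnames = list(cellIdsV, paste0("level", 1:4)))
    lv[, 1] <- z
    sub2 <- paste0(z, letters[1 + (stats::runif(nCells) < 0.5)])
    lv[, 2] <- sub2
    deep <- endsWith(sub2, "a")
    lv[deep, 3] <- paste0(sub2[deep], ".", 1 + (stats::runif(sum(deep)) < 0.5))
    deepest <- deep & endsWith(lv[, 3], ".1")
    lv[deepest, 4] <- paste0(lv[deepest, 3], ".x")
    list(z = z, counts = counts, lv = propagateLabels(lv))
  })

  labels <- S4Vectors::DataFrame(res$lv, row.names = cellIdsV)
  S4Vectors::metadata(labels)$classesLevel1 <- sort(types)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(res$counts, sparse = TRUE),
                                       "CsparseMatrix")),
    colData = labels)
  truth <- list(markers = markers, type = stats::setNames(res$z, cellIdsV),
                params = list(nCells = nCells, nGenes = nGenes,
                              nTypes = nTypes, markersPerType = markersPerType,
                              foldChange = foldChange, baseMean = baseMean,
                              dispersion = dispersion,
                              dropoutRate = dropoutRate,
                              typeProportions = typeProportions, seed = seed))
  keep <- geneIdsV
  if (vocabDropFrac > 0) {
    nDrop <- floor(nGenes * vocabDropFrac)
    keep <- setdiff(geneIdsV,
                    withSeed(childSeed(seed, 42L),
                             sample(geneIdsV, nDrop)))
  }
  emb <- simulateGeneEmbeddings(truth, dEmbed = dEmbed,
                                withinSim = withinSim,
                                geneIds = keep,
                                seed = childSeed(seed, 77L))
  list(sce = sce, labels = labels, truth = truth, embeddings = emb)
}

#' Generate a Gene2vec-style embedding table for a planted-marker truth
#'
#' Markers of the same type share a latent direction: each marker vector
#' is `sqrt(withinSim) * u_type + sqrt(1 - withinSim) * noise` with
#' orthonormal module directions `u_type` (QR of a seeded Gaussian), so
#' the expected pairwise cosine within a module is `withinSim` and about
#' 0 between modules. Non-marker genes are isotropic Gaussian.
#'
#' @param truth truth list from [simulateCells()] (needs `$markers`).
#' @param dEmbed embedding dimension (must be >= number of modules).
#' @param withinSim within-module similarity target in (0, 1).
#' @param geneIds gene ids to include (default: all genes in `truth`).
#' @param seed integer seed.
#' @return a [GeneEmbeddings-class].
#' @export
simulateGeneEmbeddings <- function(truth, dEmbed = 32L, withinSim = 0.7,
                                   geneIds = NULL, seed = 1L) {
  if (withinSim <= 0 || withinSim >= 1)
    stop("withinSim must be in (0, 1)", call. = FALSE)
  markers <- truth$markers
  nTypes <- length(markers)
  if (dEmbed < nTypes)
    stop(sprintf("dEmbed = %d too small for %d marker modules", dEmbed, nTypes),
         call. = FALSE)
  allGenes <- if (is.null(geneIds)) {
    ids <- unique(c(unlist(markers)))
    # default to every gene the truth's matrix dimension implies
    sprintf("G%04d", seq_len(truth$params$nGenes))
  } else geneIds
  V <- withSeed(seed, {
    U <- qr.Q(qr(matrix(stats::rnorm(dEmbed * nTypes), dEmbed, nTypes)))
    v <- matrix(stats::rnorm(length(allGenes) * dEmbed, sd = 1 / sqrt(dEmbed)),
                length(allGenes), dEmbed, dimnames = list(allGenes, NULL))
    for (ti in seq_along(markers)) {
      gi <- match(intersect(markers[[ti]], allGenes), allGenes)
      if (!length(gi)) next
      noise <- matrix(stats::rnorm(length(gi) * dEmbed, sd = 1 / sqrt(dEmbed)),
                      length(gi), dEmbed)
      v[gi, ] <- sqrt(withinSim) * matrix(U[, ti], length(gi), dEmbed,
                                          byrow = TRUE) +
                 sqrt(1 - withinSim) * noise
    }
    v
  })
  methods::new("GeneEmbeddings", ids = allGenes, vectors = V)
}
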