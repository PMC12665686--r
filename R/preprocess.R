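#' Filter genes against the embedding vocabulary
#'
#' Retains genes that (a) are expressed in at least one cell and (b) have a
#' vector in the embedding table, preserving the original gene order. This
#' is the knowledge-based feature-selection step: the embedding vocabulary
#' restricts the model to characterized genes, and silent genes carry no
#' trainable signal. No highly-variable-gene selection and no
#' dimensionality reduction are performed — the architecture is built to
#' take the full filtered gene sequence.
#'
#' @param sce `SingleCellExperiment` with a `counts` assay (genes x cells).
#' @param vocab a [GeneEmbeddings-class] giving the allowed vocabulary.
#' @return the filtered `SingleCellExperiment`; `metadata()$geneFilter`
#'   reports counts of genes dropped by each rule.
#' @export
filterGenes <- function(sce, vocab) {
  m <- SummarizedExperiment::assay(sce, "counts")
  expressed <- Matrix::rowSums(m != 0) > 0
  inVocab <- rownames(sce) %in% vocab@ids
  keep <- expressed & inVocab
  if (!any(keep))
    stop("no genes retained; check that the embedding vocabulary matches the matrix gene ids",
         call. = FALSE)
  out <- sce[keep, ]
  S4Vectors::metadata(out)$geneFilter <- list(
    nInput = nrow(sce),
    nRetained = sum(keep),
    nNotExpressed = sum(!expressed),
    nOutOfVocab = sum(!inVocab),
    retained = rownames(sce)[keep]
  )
  out
}

#' Fit an expression binning scheme
#'
#' Edges are empirical quantiles of the transformed *nonzero* values, so
#' the nonzero mass is spread roughly uniformly across bins `1..nBins-1`;
#' bin 0 is reserved for exactly-zero expression. Edges are the upper
#' quantile boundaries at probabilities `1/(B-1), ..., 1` and are frozen
#' after fitting (serialize with [writeBinningScheme()]); fit them on
#' training cells only.
#'
#' @param sce `SingleCellExperiment` (or a plain matrix of non-negative
#'   values, any orientation) to fit on.
#' @param nBins number of bins B >= 2 including the zero bin.
#' @param transform `"log1p"` (default) or `"identity"`.
#' @param perGene fit a separate edge set per gene (genes = rows of the
#'   assay)? Default global: one shared edge set.
#' @return a [BinningScheme-class].
#' @export
fitBins <- function(sce, nBins = 7L, transform = c("log1p", "identity"),
                    perGene = FALSE) {
  transform <- match.arg(transform)
  nBins <- as.integer(nBins)
  if (nBins < 2L) stop("nBins must be >= 2", call. = FALSE)
  m <- if (methods::is(sce, "SummarizedExperiment"))
    SummarizedExperiment::assay(sce, "counts") else sce
  tf <- if (transform == "log1p") log1p else identity
  probs <- seq_len(nBins - 1L) / (nBins - 1L)
  if (perGene) {
    edges <- t(apply(as.matrix(m), 1L, function(row) {
      nz <- row[row > 0]
      if (!length(nz)) return(rep(NA_real_, nBins - 1L))
      stats::quantile(tf(nz), probs = probs, names = FALSE, type = 7)
    }))
    if (all(is.na(edges))) stop("all values are zero; nothing to bin", call. = FALSE)
    rownames(edges) <- rownames(m)
  } else {
    nz <- if (methods::is(m, "sparseMatrix")) m@x[m@x > 0] else m[m > 0]
    if (!length(nz)) stop("all values are zero; nothing to bin", call. = FALSE)
    edges <- stats::quantile(tf(nz), probs = probs, names = FALSE, type = 7)
  }
  methods::new("BinningScheme", nBins = nBins, edges = edges,
               transform = transform, perGene = perGene)
}

#' Map non-negative values to bin ids
#'
#' Zero maps to bin 0; a positive value v maps to
#' `min(B-1, 1 + #(edges < t(v)))`, i.e. 1 plus the quantile interval that
#' contains it, clamped so values beyond the training maximum fall in the
#' top bin. Monotone in v by construction.
#'
#' @param values numeric vector of non-negative expression values.
#' @param scheme a [BinningScheme-class].
#' @param gene gene index (row of the per-gene edge matrix); required when
#'   the scheme was fitted per gene.
#' @return integer bin ids in `0..nBins-1`.
#' @export
binValues <- function(values, scheme, gene = NULL) {
  if (any(values < 0)) {
    bad <- which(values < 0)[1]
    stop(sprintf("negative expression value %g at position %d", values[bad], bad),
         call. = FALSE)
  }
  edges <- if (scheme@perGene) {
    if (is.null(gene)) stop("per-gene scheme requires gene=", call. = FALSE)
    e <- scheme@edges[gene, ]
    if (all(is.na(e))) e <- rep(Inf, scheme@nBins - 1L)  # never-expressed gene
    e
  } else scheme@edges
  tf <- if (scheme@transform == "log1p") log1p else identity
  out <- integer(length(values))
  pos <- values > 0
  if (any(pos)) {
    tv <- tf(values[pos])
    # edges are upper boundaries (inclusive): bin = 1 + #(edges < t(v))
    ids <- 1L + findInterval(tv, edges, left.open = TRUE)
    out[pos] <- pmin(ids, scheme@nBins - 1L)
  }
  out
}

#' Tokenize cells into fixed-order gene/bin sequences
#'
#' Every cell becomes the same ordered gene sequence (the filtered
#' vocabulary order, which defines the positions for the positional
#' encoding) with a per-gene expression-bin id.
#'
#' @param sce filtered `SingleCellExperiment` (genes x cells).
#' @param scheme a fitted [BinningScheme-class].
#' @return a [TokenizedCells-class] (cells x genes integer bin matrix).
#' @export
tokenizeCells <- function(sce, scheme) {
  m <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
  L <- nrow(m)
  bins <- matrix(0L, ncol(m), L, dimnames = list(colnames(m), rownames(m)))
  if (scheme@perGene) {
    for (g in seq_len(L)) bins[, g] <- binValues(m[g, ], scheme, gene = g)
  } else {
    bins[] <- binValues(as.numeric(t(m)), scheme)
  }
  methods::new("TokenizedCells", bins = bins, geneIds = rownames(m),
               cellIds = colnames(m), scheme = scheme)
}

#' Serialize / deserialize a binning scheme as JSON
#' @param scheme a [BinningScheme-class].
#' @param path JSON file path.
#' @export
writeBinningScheme <- function(scheme, path) {
  jsonlite::write_json(list(
    n_bins = scheme@nBins,
    transform = scheme@transform,
    per_gene = scheme@perGene,
    edges = if (scheme@perGene) as.data.frame(scheme@edges) else scheme@edges
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeBinningScheme
#' @export
readBinningScheme <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (isTRUE(j$per_gene)) as.matrix(j$edges) else as.numeric(j$edges)
  methods::new("BinningScheme", nBins = as.integer(j$n_bins), edges = edges,
               transform = j$transform, perGene = isTRUE(j$per_gene))
}

#' Subset tokenized cells by cell id or index
#' @param tokens a [TokenizedCells-class].
#' @param cells character ids or integer indices.
#' @return a [TokenizedCells-class] restricted to those cells.
#' @export
subsetCells <- function(tokens, cells) {
  if (is.character(cells)) cells <- match(cells, tokens@cellIds)
  if (anyNA(cells)) stop("unknown cell id(s)", call. = FALSE)
  methods::new("TokenizedCells",
    bins = tokens@bins[cells, , drop = FALSE],
    geneIds = tokens@geneIds,
    cellIds = tokens@cellIds[cells],
    scheme = tokens@scheme)
}
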