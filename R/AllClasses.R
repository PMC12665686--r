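#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Binning scheme for expression tokenization
#'
#' Discretizes expression values into `nBins` categories. Bin 0 is reserved
#' for exactly-zero expression; nonzero values are assigned to bins
#' `1..nBins-1` by comparing the transformed value against `edges`, the
#' upper quantile boundaries fitted on training data. `edges` has length
#' `nBins - 1` for global binning, or is a genes x (nBins-1) matrix when
#' fitted per gene.
#'
#' @slot nBins integer number of bins B (>= 2), including the zero bin.
#' @slot edges numeric vector (global) or matrix (per-gene) of strictly
#'   increasing thresholds on the transformed scale.
#' @slot transform one of `"log1p"` or `"identity"`.
#' @slot perGene logical; were edges fitted per gene?
#' @exportClass BinningScheme
setClass("BinningScheme",
  representation(
    nBins = "integer",
    edges = "ANY",
    transform = "character",
    perGene = "logical"
  )
)

setValidity("BinningScheme", function(object) {
  msg <- NULL
  if (length(object@nBins) != 1L || object@nBins < 2L)
    msg <- c(msg, "nBins must be a single integer >= 2")
  if (!object@transform %in% c("log1p", "identity"))
    msg <- c(msg, "transform must be 'log1p' or 'identity'")
  ed <- object@edges
  if (object@perGene) {
    if (!is.matrix(ed) || ncol(ed) != object@nBins - 1L)
      msg <- c(msg, "per-gene edges must be a genes x (nBins-1) matrix")
  } else {
    if (!is.numeric(ed) || length(ed) != object@nBins - 1L)
      msg <- c(msg, "edges must have length nBins - 1")
    if (length(ed) > 1L && any(diff(ed) < 0))
      msg <- c(msg, "edges must be non-decreasing")
  }
  if (is.null(msg)) TRUE else msg
})

#' Tokenized cells
#'
#' Each cell is an ordered sequence of (gene, expression-bin) tokens over a
#' fixed gene vocabulary; the shared order defines the positions used by
#' the positional encoding.
#'
#' @slot bins integer matrix, cells x genes, values in `0..nBins-1`.
#' @slot geneIds character vector of the gene vocabulary (column order).
#' @slot cellIds character vector of cell identifiers (row order).
#' @slot scheme the [BinningScheme-class] used to produce the bins.
#' @exportClass TokenizedCells
setClass("TokenizedCells",
  representation(
    bins = "matrix",
    geneIds = "character",
    cellIds = "character",
    scheme = "BinningScheme"
  )
)

setValidity("TokenizedCells", function(object) {
  msg <- NULL
  if (!is.integer(object@bins[1, 1, drop = TRUE]) && !is.numeric(object@bins))
    msg <- c(msg, "bins must be numeric/integer")
  if (ncol(object@bins) != length(object@geneIds))
    msg <- c(msg, "ncol(bins) must equal length(geneIds)")
  if (nrow(object@bins) != length(object@cellIds))
    msg <- c(msg, "nrow(bins) must equal length(cellIds)")
  if (anyDuplicated(object@geneIds)) msg <- c(msg, "duplicate gene ids")
  if (anyDuplicated(object@cellIds)) msg <- c(msg, "duplicate cell ids")
  rng <- range(object@bins)
  if (rng[1] < 0 || rng[2] > object@scheme@nBins - 1L)
    msg <- c(msg, "bin ids must lie in [0, nBins-1]")
  if (is.null(msg)) TRUE else msg
})

#' Gene embedding table
#'
#' Gene2vec-style table mapping gene symbols to dense vectors; functionally
#' related genes are expected to be close in this space. Used both as the
#' vocabulary filter and to initialize the encoder's gene-identity
#' embeddings.
#'
#' @slot ids character gene identifiers (unique).
#' @slot vectors numeric matrix genes x dEmbed, finite.
#' @exportClass GeneEmbeddings
setClass("GeneEmbeddings",
  representation(ids = "character", vectors = "matrix")
)

setValidity("GeneEmbeddings", function(object) {
  msg <- NULL
  if (nrow(object@vectors) != length(object@ids))
    msg <- c(msg, "one vector per gene id required")
  if (anyDuplicated(object@ids)) msg <- c(msg, "duplicate gene ids")
  if (length(object@vectors) && !all(is.finite(object@vectors)))
    msg <- c(msg, "non-finite embedding entries")
  if (is.null(msg)) TRUE else msg
})

#' Train/validation/test split assignment
#'
#' @slot partition factor with levels `train`, `val`, `test`, named by cell id.
#' @slot ratios numeric length-3 ratios summing to 1.
#' @slot seed integer seed used for the assignment.
#' @slot stratified logical; was the split stratified by level-1 label?
#' @exportClass SplitAssignment
setClass("SplitAssignment",
  representation(
    partition = "factor",
    ratios = "numeric",
    seed = "integer",
    stratified = "logical"
  )
)

setValidity("SplitAssignment", function(object) {
  msg <- NULL
  if (!identical(levels(object@partition), c("train", "val", "test")))
    msg <- c(msg, "partition levels must be train/val/test")
  if (length(object@ratios) != 3L || abs(sum(object@ratios) - 1) > 1e-8)
    msg <- c(msg, "ratios must be length 3 and sum to 1")
  if (is.null(names(object@partition)))
    msg <- c(msg, "partition must be named by cell id")
  if (is.null(msg)) TRUE else msg
})

#' Reformer encoder configuration
#'
#' Architecture hyperparameters. Defaults follow the published setup
#' (d_model 200, 6 layers, 10 heads, 64 LSH buckets) but every test-scale
#' configuration is expressible.
#'
#' @slot dModel embedding/feature width (divisible by nHeads).
#' @slot nLayers number of reversible (attention, feed-forward) blocks.
#' @slot nHeads attention heads.
#' @slot nBuckets LSH buckets (1 = single bucket = exact full attention;
#'   otherwise must be even, for the `[xR, -xR]` rotation construction).
#' @slot nHashRounds number of independent hash rounds; candidate sets are
#'   unioned over rounds.
#' @slot nBins expression-bin vocabulary size B (bin 0 = zero expression);
#'   the MASK token gets id B.
#' @slot seqLen gene-sequence length L (size of the filtered vocabulary).
#' @slot dropout dropout rate applied in the classification head.
#' @slot dFf feed-forward hidden width.
#' @slot convChannels channels of the per-gene 1-D convolution head.
#' @slot hiddenSizes integer length-2 hidden sizes of the 3-layer MLP head.
#' @slot attention `"lsh"` or `"full"` (full is the ablation oracle).
#' @slot allowSelf may a position attend to itself? Default TRUE so that the
#'   single-bucket limit reproduces full attention exactly.
#' @exportClass ReformerConfig
setClass("ReformerConfig",
  representation(
    dModel = "integer", nLayers = "integer", nHeads = "integer",
    nBuckets = "integer", nHashRounds = "integer", nBins = "integer",
    seqLen = "integer", dropout = "numeric", dFf = "integer",
    convChannels = "integer", hiddenSizes = "integer",
    attention = "character", allowSelf = "logical"
  )
)

setValidity("ReformerConfig", function(object) {
  msg <- NULL
  if (object@dModel %% object@nHeads != 0L)
    msg <- c(msg, "dModel must be divisible by nHeads")
  if (object@nBuckets != 1L && object@nBuckets %% 2L != 0L)
    msg <- c(msg, "nBuckets must be 1 or even")
  if (object@seqLen < 1L) msg <- c(msg, "seqLen must be >= 1")
  if (object@nBins < 2L) msg <- c(msg, "nBins must be >= 2")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must be in [0, 1)")
  if (!object@attention %in% c("lsh", "full"))
    msg <- c(msg, "attention must be 'lsh' or 'full'")
  if (length(object@hiddenSizes) != 2L)
    msg <- c(msg, "hiddenSizes must have length 2")
  if (is.null(msg)) TRUE else msg
})

#' A (possibly trained) Reformer model
#'
#' Bundles the configuration, all parameter tensors, the frozen binning
#' scheme and gene vocabulary, the level-1 class set once fine-tuned, and
#' training history.
#'
#' @slot config [ReformerConfig-class].
#' @slot params nested list of parameter matrices (see `initReformer`).
#' @slot scheme [BinningScheme-class] or NULL before preprocessing is bound.
#' @slot geneIds gene vocabulary in sequence order.
#' @slot classes character level-1 class labels (empty until fine-tuned).
#' @slot history data.frame of per-epoch training diagnostics.
#' @exportClass ReformerModel
setClass("ReformerModel",
  representation(
    config = "ReformerConfig",
    params = "list",
    scheme = "ANY",
    geneIds = "character",
    classes = "character",
    history = "data.frame"
  )
)

#' Classification metrics report
#'
#' @slot confusion C x C integer matrix, rows = true class, cols = predicted.
#' @slot accuracy overall accuracy in [0, 1].
#' @slot macroF1 unweighted mean of per-class F1 scores.
#' @slot perClassAUC named numeric one-vs-rest AUC per class (NA if the
#'   class is absent from the truth).
#' @slot classes class labels, in confusion-matrix order.
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(
    confusion = "matrix",
    accuracy = "numeric",
    macroF1 = "numeric",
    perClassAUC = "numeric",
    classes = "character"
  )
)

setValidity("MetricsReport", function(object) {
  msg <- NULL
  if (nrow(object@confusion) != ncol(object@confusion))
    msg <- c(msg, "confusion matrix must be square")
  if (any(object@confusion < 0)) msg <- c(msg, "confusion entries must be >= 0")
  tot <- sum(object@confusion)
  if (tot > 0 && abs(object@accuracy - sum(diag(object@confusion)) / tot) > 1e-8)
    msg <- c(msg, "accuracy must equal trace/sum of the confusion matrix")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: %d classes, %d cells\n",
              length(object@classes), sum(object@confusion)))
  cat(sprintf("  accuracy : %.1f%%\n", 100 * object@accuracy))
  cat(sprintf("  macro F1 : %.1f%%\n", 100 * object@macroF1))
  auc <- object@perClassAUC
  cat("  one-vs-rest AUC:\n")
  for (i in seq_along(auc))
    cat(sprintf("    %-20s %s\n", names(auc)[i],
                ifelse(is.na(auc[i]), "NA (class absent)",
                       sprintf("%.3f", auc[i]))))
  invisible(object)
})

setMethod("show", "ReformerModel", function(object) {
  cfg <- object@config
  cat(sprintf("ReformerModel: L=%d genes, d=%d, %d layers, %d heads, %s attention (%d buckets)\n",
              cfg@seqLen, cfg@dModel, cfg@nLayers, cfg@nHeads,
              cfg@attention, cfg@nBuckets))
  if (length(object@classes))
    cat("  fine-tuned classes:", paste(object@classes, collapse = ", "), "\n")
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs (last monitored loss %.4f)\n",
                nrow(object@history),
                object@history[nrow(object@history), ncol(object@history)]))
  invisible(object)
})

setMethod("show", "TokenizedCells", function(object) {
  cat(sprintf("TokenizedCells: %d cells x %d genes, %d bins (%s)\n",
              nrow(object@bins), ncol(object@bins), object@scheme@nBins,
              object@scheme@transform))
  invisible(object)
})

setMethod("show", "BinningScheme", function(object) {
  cat(sprintf("BinningScheme: %d bins (bin 0 = zero), transform %s, %s edges\n",
              object@nBins, object@transform,
              if (object@perGene) "per-gene" else "global"))
  invisible(object)
})

#' Accessors for tokenized cells and models
#'
#' @param x a TokenizedCells, GeneEmbeddings or ReformerModel object.
#' @return `tokenBins` the integer bin matrix; `geneIds` the gene
#'   vocabulary; `cellIds` cell identifiers; `binningScheme` the scheme;
#'   `modelConfig` the encoder configuration; `modelClasses` the fine-tuned
#'   class labels; `trainingHistory` the per-epoch diagnostics;
#'   `embeddingVectors` the embedding matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
tokenBins <- function(x) x@bins

#' @rdname accessors
#' @export
geneIds <- function(x) x@geneIds

#' @rdname accessors
#' @export
cellIds <- function(x) x@cellIds

#' @rdname accessors
#' @export
binningScheme <- function(x) x@scheme

#' @rdname accessors
#' @export
modelConfig <- function(x) x@config

#' @rdname accessors
#' @export
modelClasses <- function(x) x@classes

#' @rdname accessors
#' @export
trainingHistory <- function(x) x@history

#' @rdname accessors
#' @export
embeddingVectors <- function(x) x@vectors

#' @rdname accessors
#' @export
embeddingIds <- function(x) x@ids
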