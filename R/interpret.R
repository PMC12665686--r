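#' Sampling-based Shapley attribution
#'
#' Model-agnostic permutation estimator of Shapley values. For each
#' sampled permutation a background cell is drawn, features of the
#' explained cell are switched on in permutation order, and each
#' feature's marginal change in model output is recorded; averaging over
#' samples yields additive attributions satisfying (in expectation) local
#' accuracy: the attributions sum to f(x) minus the expected output over
#' the background. Here a "feature" is a gene's bin token and background
#' replacement substitutes the background cell's bin at that gene, which
#' respects the discreteness of the tokenization.
#'
#' @param f vectorized model function: takes a matrix of token rows and
#'   returns one numeric output per row (e.g. a class logit).
#' @param x integer/numeric feature vector of the cell to explain.
#' @param background matrix of background rows (the reference
#'   distribution; the published protocol samples 500 training cells).
#' @param nSamples number of permutation samples (>= 1).
#' @param seed integer seed.
#' @return numeric vector of per-feature attributions (length of x).
#' @export
shapSample <- function(f, x, background, nSamples = 100L, seed = 1L) {
  if (!nrow(background)) stop("empty background set", call. = FALSE)
  L <- length(x)
  phi <- numeric(L)
  withSeed(seed, {
    for (s in seq_len(nSamples)) {
      b <- background[sample.int(nrow(background), 1L), ]
      perm <- sample.int(L)
      # L+1 hybrids: row k has the first k-1 features of the permutation
      # already switched from background to x
      hyb <- matrix(rep(b, L + 1L), L + 1L, L, byrow = TRUE)
      for (k in seq_len(L)) {
        rows <- (k + 1L):(L + 1L)
        hyb[rows, perm[k]] <- x[perm[k]]
      }
      out <- f(hyb)
      phi[perm] <- phi[perm] + diff(out)
    }
  })
  phi / nSamples
}

#' Gene attributions for one class of a fine-tuned model
#'
#' Runs [shapSample()] for each explained cell against the pre-softmax
#' logit of `targetClass` (logits are stable under class-count changes,
#' unlike probabilities). Background and explained cells follow the
#' published protocol (a background of training cells representing the
#' expected expression distribution, explained cells drawn from the class
#' of interest), scaled to the data at hand.
#'
#' @param model fine-tuned [ReformerModel-class].
#' @param tokens [TokenizedCells-class].
#' @param targetClass class label (or 1-based index) to explain.
#' @param backgroundIdx cell indices serving as background.
#' @param explainIdx cell indices to explain.
#' @param nSamples permutation samples per cell.
#' @param seed integer seed.
#' @return list with `attributions` (cells x genes matrix),
#'   `meanAbs` (per-gene mean absolute attribution), `meanSigned`,
#'   `expectedLogit` (mean background logit) and `geneIds`.
#' @export
explainReformer <- function(model, tokens, targetClass, backgroundIdx,
                            explainIdx, nSamples = 20L, seed = 1L) {
  if (!length(backgroundIdx)) stop("empty background set", call. = FALSE)
  cls <- if (length(model@classes)) model@classes
         else as.character(seq_along(model@params$clsHead$b3))
  ci <- if (is.numeric(targetClass)) as.integer(targetClass)
        else match(as.character(targetClass), cls)
  if (is.na(ci) || ci < 1L || ci > length(cls))
    stop("target class out of range", call. = FALSE)
  f <- function(binsMat) {
    vapply(seq_len(nrow(binsMat)), function(i) {
      H <- encoderForward(as.integer(binsMat[i, ]), model@params,
                          model@config, seed = 1L)$H
      clsHeadForward(H, model@params, model@config)$logits[ci]
    }, numeric(1))
  }
  bg <- tokens@bins[backgroundIdx, , drop = FALSE]
  attr <- matrix(0, length(explainIdx), ncol(tokens@bins),
                 dimnames = list(tokens@cellIds[explainIdx], tokens@geneIds))
  for (j in seq_along(explainIdx)) {
    attr[j, ] <- shapSample(f, tokens@bins[explainIdx[j], ], bg,
                            nSamples = nSamples,
                            seed = childSeed(seed, j))
  }
  list(attributions = attr,
       meanAbs = colMeans(abs(attr)),
       meanSigned = colMeans(attr),
       expectedLogit = mean(f(bg)),
       geneIds = tokens@geneIds)
}

#' Top genes by mean absolute attribution
#'
#' Descending by mean |attribution|; ties broken by gene index.
#'
#' @param result output of [explainReformer()] (or any list with
#'   `meanAbs`, `meanSigned`, `geneIds`).
#' @param k number of genes to return (<= number of genes).
#' @return data.frame with `gene`, `meanAbs`, `meanSigned`, in rank order.
#' @export
topGenes <- function(result, k) {
  L <- length(result$meanAbs)
  if (k > L) stop("k exceeds the number of genes", call. = FALSE)
  ord <- order(-result$meanAbs, seq_len(L))
  idx <- ord[seq_len(k)]
  data.frame(gene = result$geneIds[idx],
             meanAbs = unname(result$meanAbs[idx]),
             meanSigned = unname(result$meanSigned[idx]))
}
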