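#' Construct a Reformer encoder configuration
#'
#' Defaults mirror the published architecture (feature width 200, 6
#' layers, 10 heads, 64 LSH buckets); the head/bin/sequence sizes come
#' from the data. Test-scale models simply pass smaller values.
#'
#' @param seqLen gene-sequence length L (filtered vocabulary size).
#' @param nBins expression-bin count B (incl. the zero bin).
#' @param dModel feature width (divisible by `nHeads`).
#' @param nLayers reversible blocks.
#' @param nHeads attention heads.
#' @param nBuckets LSH buckets (1 = exact full attention).
#' @param nHashRounds hash rounds unioned into the candidate sets.
#' @param dropout classification-head dropout rate.
#' @param dFf feed-forward hidden width (default 2 x dModel).
#' @param convChannels channels of the per-gene conv head (default dModel).
#' @param hiddenSizes hidden sizes of the 3-layer MLP head.
#' @param attention `"lsh"` or `"full"` (the ablation switch).
#' @param allowSelf allow self-attention (see [lshAttention()]).
#' @return a [ReformerConfig-class].
#' @export
reformerConfig <- function(seqLen, nBins = 7L, dModel = 200L, nLayers = 6L,
                           nHeads = 10L, nBuckets = 64L, nHashRounds = 4L,
                           dropout = 0.1, dFf = 2L * dModel,
                           convChannels = dModel,
                           hiddenSizes = c(512L, 512L),
                           attention = c("lsh", "full"), allowSelf = TRUE) {
  attention <- match.arg(attention)
  methods::new("ReformerConfig",
    dModel = as.integer(dModel), nLayers = as.integer(nLayers),
    nHeads = as.integer(nHeads), nBuckets = as.integer(nBuckets),
    nHashRounds = as.integer(nHashRounds), nBins = as.integer(nBins),
    seqLen = as.integer(seqLen), dropout = as.numeric(dropout),
    dFf = as.integer(dFf), convChannels = as.integer(convChannels),
    hiddenSizes = as.integer(hiddenSizes), attention = attention,
    allowSelf = allowSelf)
}

#' Initialize a Reformer model
#'
#' Gene-identity embeddings are initialized from the embedding table when
#' one is supplied (requiring `dEmbed == dModel`) and remain trainable;
#' otherwise they are random. The bin-embedding table has `nBins + 1`
#' rows: bins `0..B-1` plus the reserved MASK token (id B). Positional
#' encodings are fixed sinusoids.
#'
#' @param config a [ReformerConfig-class].
#' @param geneIds gene vocabulary in sequence order (length `seqLen`).
#' @param embeddings optional [GeneEmbeddings-class] for initialization.
#' @param scheme optional [BinningScheme-class] to freeze into the model.
#' @param seed integer seed for the random initialization.
#' @param nClasses if > 0, also initialize the classification head.
#' @return an (untrained) [ReformerModel-class].
#' @export
initReformer <- function(config, geneIds, embeddings = NULL, scheme = NULL,
                         seed = 2022L, nClasses = 0L) {
  cfg <- config
  if (length(geneIds) != cfg@seqLen)
    stop("length(geneIds) must equal config seqLen", call. = FALSE)
  params <- withSeed(seed, {
    d <- cfg@dModel
    geneEmb <- if (!is.null(embeddings)) {
      if (ncol(embeddings@vectors) != d)
        stop(sprintf("embedding dim %d does not match dModel %d",
                     ncol(embeddings@vectors), d), call. = FALSE)
      idx <- match(geneIds, embeddings@ids)
      if (anyNA(idx))
        stop("gene(s) missing from the embedding table: ",
             paste(utils::head(geneIds[is.na(idx)]), collapse = ", "),
             call. = FALSE)
      embeddings@vectors[idx, , drop = FALSE]
    } else {
      matrix(stats::rnorm(cfg@seqLen * d, sd = 0.02), cfg@seqLen, d)
    }
    rownames(geneEmb) <- geneIds
    p <- list(
      geneEmb = geneEmb,
      # unit-norm rows: the expression-bin component enters the summed
      # input embedding on the same scale as the gene-identity vectors
      # and the sinusoidal positional term
      binEmb = matrix(stats::rnorm((cfg@nBins + 1L) * d, sd = 1 / sqrt(d)),
                      cfg@nBins + 1L, d),
      layers = lapply(seq_len(cfg@nLayers), function(l) initLayerParams(cfg)),
      mlmHead = list(Wr = xavier(d, cfg@nBins), br = rep(0, cfg@nBins)),
      posEnc = sinusoidalEncoding(cfg@seqLen, d)
    )
    if (nClasses > 0L) p$clsHead <- initClsHead(cfg, nClasses)
    p
  })
  methods::new("ReformerModel", config = cfg, params = params,
               scheme = scheme, geneIds = as.character(geneIds),
               classes = character(), history = data.frame())
}

initClsHead <- function(cfg, nClasses) {
  d <- cfg@dModel; cc <- cfg@convChannels
  h1 <- cfg@hiddenSizes[1]; h2 <- cfg@hiddenSizes[2]
  list(Wc = xavier(d, cc), bc = rep(0, cc),
       W1 = xavier(2L * cc, h1), b1 = rep(0, h1),
       W2 = xavier(h1, h2), b2 = rep(0, h2),
       W3 = xavier(h2, nClasses), b3 = rep(0, nClasses))
}

#' Input embedding of one tokenized cell
#'
#' The per-gene input vector is the sum of three components: the gene
#' identity embedding, the expression-bin embedding, and the sinusoidal
#' positional encoding.
#'
#' @param model a [ReformerModel-class].
#' @param bins integer vector of length L with bin ids in `0..B` (B = MASK).
#' @return L x dModel numeric matrix.
#' @export
embedTokens <- function(model, bins) {
  cfg <- model@config
  if (length(bins) != cfg@seqLen) stop("bins length must equal seqLen", call. = FALSE)
  if (any(bins < 0) || any(bins > cfg@nBins))
    stop("bin id out of range [0, nBins] (nBins = MASK token)", call. = FALSE)
  embedForwardBins(as.integer(bins), model@params)
}

#' Encode one cell to per-gene features
#'
#' Input embeddings pass through `nLayers` reversible blocks of
#' (multi-head LSH attention, feed-forward); the output is the mean of the
#' two reversible half-states, an L x dModel per-gene feature matrix.
#' Deterministic in evaluation mode for a fixed seed.
#'
#' @param model a [ReformerModel-class].
#' @param bins integer token vector (length L).
#' @param seed seed for the hash rotations.
#' @return L x dModel feature matrix.
#' @export
encodeCell <- function(model, bins, seed = 1L) {
  encoderForward(as.integer(bins), model@params, model@config, seed = seed)$H
}

# ---- masking + losses -------------------------------------------------

#' Mask expressed genes of tokenized cells
#'
#' Each nonzero-bin position is independently selected with probability
#' `maskProb`; a selected position is replaced by the reserved MASK token
#' with probability `replaceProb` and otherwise left unchanged (there is
#' no random-token branch). Zero-expression positions are never selected.
#' Deterministic per seed.
#'
#' @param tokens a [TokenizedCells-class] (or plain integer bin matrix).
#' @param maskProb per-position masking probability (published value 0.15).
#' @param replaceProb probability a masked position shows the MASK token
#'   (published value 0.9).
#' @param seed integer seed.
#' @return list with `bins` (masked integer matrix, MASK = nBins),
#'   `maskPos` (per-cell integer index vectors) and `targets` (per-cell
#'   true bin ids aligned with `maskPos`).
#' @export
maskCells <- function(tokens, maskProb = 0.15, replaceProb = 0.9, seed = 1L) {
  stopifnot(maskProb >= 0, maskProb <= 1, replaceProb >= 0, replaceProb <= 1)
  bins <- if (methods::is(tokens, "TokenizedCells")) tokens@bins else tokens
  MASK <- if (methods::is(tokens, "TokenizedCells")) tokens@scheme@nBins
          else max(bins) + 1L
  n <- nrow(bins)
  maskPos <- vector("list", n)
  targets <- vector("list", n)
  out <- bins
  nEmpty <- 0L
  withSeed(seed, {
    for (i in seq_len(n)) {
      nz <- which(bins[i, ] > 0L)
      if (!length(nz)) {
        nEmpty <- nEmpty + 1L
        maskPos[[i]] <- integer(0); targets[[i]] <- integer(0)
        next
      }
      sel <- nz[stats::runif(length(nz)) < maskProb]
      maskPos[[i]] <- sel
      targets[[i]] <- as.integer(bins[i, sel])
      if (length(sel)) {
        rep_ <- stats::runif(length(sel)) < replaceProb
        out[i, sel[rep_]] <- MASK
      }
    }
  })
  if (nEmpty > 0L)
    warning(sprintf("%d cell(s) have no nonzero bins; empty mask set", nEmpty))
  list(bins = out, maskPos = maskPos, targets = targets, maskToken = MASK)
}

#' Masked-reconstruction (MLM) cross-entropy loss
#'
#' `-sum_i sum_j log p_{i,j}[y_{i,j}]` over all masked genes of all cells:
#' a sum, not a mean, so a uniform predictor scores exactly
#' (number of masked genes) x log(B). Probabilities are clamped at 1e-12
#' with a warning.
#'
#' @param probs matrix with one row per masked gene, each row a
#'   probability distribution over the B bins.
#' @param targets integer true bin ids (0-based) aligned with rows.
#' @return non-negative scalar loss.
#' @export
mlmLoss <- function(probs, targets) {
  if (nrow(probs) != length(targets))
    stop("probs rows must align with targets", call. = FALSE)
  if (!nrow(probs)) return(0)
  p <- probs[cbind(seq_len(nrow(probs)), as.integer(targets) + 1L)]
  if (any(p < 1e-12)) {
    warning("predicted probability < 1e-12 at a target; clamped")
    p <- pmax(p, 1e-12)
  }
  -sum(log(p))
}

#' Classification cross-entropy loss
#'
#' `-sum_i log q_i[z_i]`: one-hot cross-entropy summed over cells; a
#' uniform classifier scores exactly m x log(C).
#'
#' @param probs cells x C matrix of predicted class probabilities.
#' @param classes integer true class indices (1-based) or factor.
#' @return non-negative scalar loss.
#' @export
clsLoss <- function(probs, classes) {
  z <- if (is.factor(classes)) as.integer(classes) else as.integer(classes)
  if (nrow(probs) != length(z))
    stop("probs rows must align with classes", call. = FALSE)
  p <- probs[cbind(seq_len(nrow(probs)), z)]
  if (any(p < 1e-12)) {
    warning("predicted probability < 1e-12 at the true class; clamped")
    p <- pmax(p, 1e-12)
  }
  -sum(log(p))
}

# ---- AdamW ------------------------------------------------------------

adamwInit <- function(params) paramMap(params, function(x) NULL)

# one AdamW step over nested parameter/gradient lists; weight decay is
# applied to matrices only (embeddings/projections), not to gains/biases
adamwStep <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, wd = 0.01) {
  if (is.list(p)) {
    out <- mapply(adamwStep, p, g, st,
                  MoreArgs = list(lr = lr, t = t, beta1 = beta1,
                                  beta2 = beta2, eps = eps, wd = wd),
                  SIMPLIFY = FALSE)
    return(list(p = lapply(out, `[[`, "p"), st = lapply(out, `[[`, "st")))
  }
  if (is.null(g)) return(list(p = p, st = st))
  if (is.null(st)) st <- list(m = g * 0, v = g * 0)
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g * g
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  decay <- if (is.matrix(p)) wd * p else 0
  p <- p - lr * (mhat / (sqrt(vhat) + eps) + decay)
  list(p = p, st = st)
}

# linear schedule with warm-up over the first `warmFrac` of total steps
lrSchedule <- function(step, total, lr, warmFrac = 0.1) {
  w <- max(1, floor(total * warmFrac))
  if (step <= w) return(lr * step / w)
  if (total <= w) return(lr)
  lr * max(0, (total - step) / (total - w))
}

# ---- gradient computation for one cell (internal, also used in tests) --

mlmCellGrad <- function(params, cfg, binsMasked, maskPos, targets,
                        seed = 1L, storeActivations = FALSE, scale = 1) {
  ef <- encoderForward(binsMasked, params, cfg, seed = seed,
                       storeActivations = storeActivations)
  hf <- mlmHeadForward(ef$H, maskPos, params)
  loss <- mlmLoss(hf$P, targets)
  hb <- mlmHeadBackward(hf$P, targets, hf$Z, maskPos, cfg@seqLen, params,
                        scale = scale)
  enc <- encoderBackward(hb$dH, ef$cache, params, cfg)
  list(loss = loss,
       grads = list(geneEmb = enc$geneEmb, binEmb = enc$binEmb,
                    layers = enc$layers, mlmHead = hb$grads))
}

clsCellGrad <- function(params, cfg, bins, classIdx, seed = 1L,
                        dropMasks = NULL, scale = 1,
                        storeActivations = FALSE) {
  ef <- encoderForward(bins, params, cfg, seed = seed,
                       storeActivations = storeActivations)
  hf <- clsHeadForward(ef$H, params, cfg, dropMasks = dropMasks)
  loss <- -log(max(hf$probs[classIdx], 1e-12))
  dlogits <- hf$probs
  dlogits[classIdx] <- dlogits[classIdx] - 1
  hb <- clsHeadBackward(dlogits * scale, hf$cache, params)
  enc <- encoderBackward(hb$dH, ef$cache, params, cfg)
  list(loss = loss,
       grads = list(geneEmb = enc$geneEmb, binEmb = enc$binEmb,
                    layers = enc$layers, clsHead = hb$grads))
}

addGrads <- function(a, b) {
  if (is.null(a)) return(b)
  paramZip(a, b, `+`)
}

# clip the global gradient norm (standard transformer-training safeguard
# against early-training overshoot)
clipGrads <- function(g, maxNorm = 1) {
  nrm <- sqrt(paramSumSq(g))
  if (is.finite(nrm) && nrm > maxNorm) g <- paramMap(g, function(x) x * (maxNorm / nrm))
  g
}

# ---- pre-training -----------------------------------------------------

#' Self-supervised masked-expression pre-training
#'
#' Masks expressed genes (fresh noise every epoch), reconstructs their
#' expression bins with a linear head on the encoder features, and
#' minimizes the reconstruction cross-entropy with AdamW under a linear
#' learning-rate schedule with 10% warm-up. A held-out fraction of cells
#' is monitored every epoch; training halts when the best monitored loss
#' has not improved by at least `minDelta` for `patience` consecutive
#' epochs, and the parameters at the best monitored loss are returned.
#' Histories record the *per-masked-gene mean* loss so values compare
#' directly with the log(B) uniform baseline.
#'
#' @param tokens a [TokenizedCells-class] of training cells (>= 2).
#' @param config a [ReformerConfig-class].
#' @param embeddings optional [GeneEmbeddings-class] initialization.
#' @param epochs maximum epochs.
#' @param batchSize cells per optimizer micro-batch.
#' @param lr peak learning rate.
#' @param gradAcc gradient-accumulation steps (published value 60).
#' @param maskProb,replaceProb masking rates (published 0.15 / 0.9).
#' @param heldoutFrac monitored held-out fraction (published 10%).
#' @param patience plateau epochs before stopping (published 5).
#' @param minDelta minimum improvement counting as progress.
#' @param seed integer seed controlling every random choice.
#' @param verbose print per-epoch losses.
#' @return a trained [ReformerModel-class]; `trainingHistory()` has
#'   columns `epoch`, `trainLoss`, `heldoutLoss`.
#' @export
pretrainReformer <- function(tokens, config, embeddings = NULL,
                             epochs = 20L, batchSize = 32L, lr = 1e-3,
                             gradAcc = 1L, maskProb = 0.15,
                             replaceProb = 0.9, heldoutFrac = 0.1,
                             patience = 5L, minDelta = 1e-4, seed = 2022L,
                             verbose = FALSE) {
  n <- nrow(tokens@bins)
  if (n < 2L) stop("need at least 2 cells to pre-train", call. = FALSE)
  cfg <- config
  model <- initReformer(cfg, tokens@geneIds, embeddings = embeddings,
                        scheme = tokens@scheme, seed = seed)
  params <- model@params
  heldIdx <- withSeed(childSeed(seed, 7L),
                      sort(sample.int(n, max(1L, floor(n * heldoutFrac)))))
  trainIdx <- setdiff(seq_len(n), heldIdx)
  heldMask <- maskCells(tokens@bins[heldIdx, , drop = FALSE],
                        maskProb, replaceProb, childSeed(seed, 8L))
  stepsPerEpoch <- ceiling(ceiling(length(trainIdx) / batchSize) / gradAcc)
  totalSteps <- epochs * stepsPerEpoch
  opt <- adamwInit(params)
  step <- 0L
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- data.frame()
  stall <- 0L
  for (ep in seq_len(epochs)) {
    em <- maskCells(tokens@bins[trainIdx, , drop = FALSE],
                    maskProb, replaceProb, childSeed(seed, 100L + ep))
    ord <- withSeed(childSeed(seed, 200L + ep), sample(seq_along(trainIdx)))
    epochLoss <- 0; epochTok <- 0L
    acc <- NULL; accBatches <- 0L
    batchStarts <- seq(1L, length(ord), by = batchSize)
    for (bi in seq_along(batchStarts)) {
      bidx <- ord[batchStarts[bi]:min(batchStarts[bi] + batchSize - 1L, length(ord))]
      nTok <- sum(lengths(em$maskPos[bidx]))
      if (nTok == 0L) next
      for (i in bidx) {
        if (!length(em$maskPos[[i]])) next
        g <- mlmCellGrad(params, cfg, em$bins[i, ], em$maskPos[[i]],
                         em$targets[[i]], seed = 1L,
                         scale = 1 / nTok, storeActivations = TRUE)
        acc <- addGrads(acc, g$grads)
        epochLoss <- epochLoss + g$loss
        epochTok <- epochTok + length(em$maskPos[[i]])
      }
      accBatches <- accBatches + 1L
      if (accBatches >= gradAcc || bi == length(batchStarts)) {
        step <- step + 1L
        lrT <- lrSchedule(step, totalSteps, lr)
        acc <- clipGrads(acc)
        upd <- adamwStep(params[c("geneEmb", "binEmb", "layers", "mlmHead")],
                         acc, opt[c("geneEmb", "binEmb", "layers", "mlmHead")],
                         lr = lrT, t = step)
        params[names(upd$p)] <- upd$p
        opt[names(upd$st)] <- upd$st
        acc <- NULL; accBatches <- 0L
      }
    }
    trainLoss <- if (epochTok) epochLoss / epochTok else NA_real_
    heldLoss <- evalMlmLoss(params, cfg, heldMask, seed = 1L)
    if (!is.finite(heldLoss) || !is.finite(trainLoss)) {
      warning("non-finite loss; aborting with last finite checkpoint")
      break
    }
    history <- rbind(history, data.frame(epoch = ep, trainLoss = trainLoss,
                                         heldoutLoss = heldLoss))
    if (verbose)
      message(sprintf("epoch %d: train %.4f heldout %.4f", ep, trainLoss, heldLoss))
    if (heldLoss < best$loss - minDelta) {
      best <- list(loss = heldLoss, params = params, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  model@params <- best$params
  model@history <- history
  model
}

evalMlmLoss <- function(params, cfg, masked, seed = 1L) {
  tot <- 0; ntok <- 0L
  for (i in seq_len(nrow(masked$bins))) {
    mp <- masked$maskPos[[i]]
    if (!length(mp)) next
    H <- encoderForward(masked$bins[i, ], params, cfg, seed = seed)$H
    hf <- mlmHeadForward(H, mp, params)
    tot <- tot + mlmLoss(hf$P, masked$targets[[i]])
    ntok <- ntok + length(mp)
  }
  if (ntok == 0L) return(NA_real_)
  tot / ntok
}

# ---- fine-tuning ------------------------------------------------------

#' Supervised fine-tuning for first-tier cell-type classification
#'
#' Attaches the per-gene conv + 3-layer MLP classification head and
#' updates *all* weights (embeddings, encoder, head) by cross-entropy with
#' AdamW. Early stopping monitors validation accuracy with the given
#' patience (published protocol: max 3 epochs, patience 1) and the
#' checkpoint with the best validation accuracy is returned.
#'
#' @param model a [ReformerModel-class] (pre-trained, or fresh from
#'   [initReformer()] for from-scratch training).
#' @param tokensTrain,tokensVal [TokenizedCells-class] partitions.
#' @param classesTrain,classesVal character/factor level-1 labels aligned
#'   with the cells of each partition.
#' @param epochs maximum epochs (published 3).
#' @param batchSize cells per micro-batch (published 6).
#' @param lr peak learning rate (published 1e-4).
#' @param gradAcc gradient-accumulation steps (published 60).
#' @param patience epochs without validation improvement before stopping.
#' @param seed integer seed.
#' @param verbose print per-epoch diagnostics.
#' @return a [ReformerModel-class] with classes bound and history columns
#'   `epoch`, `trainLoss`, `valAccuracy`.
#' @export
finetuneReformer <- function(model, tokensTrain, classesTrain,
                             tokensVal, classesVal,
                             epochs = 3L, batchSize = 6L, lr = 1e-4,
                             gradAcc = 1L, patience = 1L, seed = 2022L,
                             verbose = FALSE) {
  cfg <- model@config
  classes <- sort(unique(as.character(classesTrain)))
  zTrain <- match(as.character(classesTrain), classes)
  zVal <- match(as.character(classesVal), classes)
  if (anyNA(zVal))
    stop("class present in validation but absent from training: ",
         paste(unique(classesVal[is.na(zVal)]), collapse = ", "), call. = FALSE)
  params <- model@params
  if (is.null(params$clsHead))
    params$clsHead <- withSeed(childSeed(seed, 11L),
                               initClsHead(cfg, length(classes)))
  n <- nrow(tokensTrain@bins)
  # frozen standardization of the pooled conv features, fitted once on
  # (a subset of) the training cells with the initial parameters
  normIdx <- withSeed(childSeed(seed, 12L), sample.int(n, min(n, 160L)))
  P0 <- t(vapply(normIdx, function(i)
    rawPooledFeatures(params, cfg, tokensTrain@bins[i, ], seed = 1L),
    numeric(2L * cfg@convChannels)))
  params$clsNorm <- list(mu = colMeans(P0),
                         sd = pmax(apply(P0, 2L, stats::sd), 1e-4))
  stepsPerEpoch <- ceiling(ceiling(n / batchSize) / gradAcc)
  totalSteps <- epochs * stepsPerEpoch
  opt <- adamwInit(params)
  step <- 0L
  best <- list(acc = -Inf, params = params, epoch = 0L)
  history <- data.frame()
  stall <- 0L
  pnames <- c("geneEmb", "binEmb", "layers", "clsHead")
  for (ep in seq_len(epochs)) {
    ord <- withSeed(childSeed(seed, 300L + ep), sample.int(n))
    epochLoss <- 0
    acc <- NULL; accBatches <- 0L
    batchStarts <- seq(1L, n, by = batchSize)
    dropSeed <- childSeed(seed, 400L + ep)
    di <- 0L
    for (bi in seq_along(batchStarts)) {
      bidx <- ord[batchStarts[bi]:min(batchStarts[bi] + batchSize - 1L, n)]
      for (i in bidx) {
        di <- di + 1L
        dm <- if (cfg@dropout > 0) withSeed(childSeed(dropSeed, di), {
          p <- cfg@dropout
          list(p0 = stats::rbinom(2L * cfg@convChannels, 1, 1 - p) / (1 - p),
               p1 = stats::rbinom(cfg@hiddenSizes[1], 1, 1 - p) / (1 - p),
               p2 = stats::rbinom(cfg@hiddenSizes[2], 1, 1 - p) / (1 - p))
        }) else NULL
        g <- clsCellGrad(params, cfg, tokensTrain@bins[i, ], zTrain[i],
                         seed = 1L, dropMasks = dm,
                         scale = 1 / length(bidx), storeActivations = TRUE)
        acc <- addGrads(acc, g$grads)
        epochLoss <- epochLoss + g$loss
      }
      accBatches <- accBatches + 1L
      if (accBatches >= gradAcc || bi == length(batchStarts)) {
        step <- step + 1L
        lrT <- lrSchedule(step, totalSteps, lr)
        acc <- clipGrads(acc)
        upd <- adamwStep(params[pnames], acc, opt[pnames], lr = lrT, t = step)
        params[names(upd$p)] <- upd$p
        opt[names(upd$st)] <- upd$st
        acc <- NULL; accBatches <- 0L
      }
    }
    tmp <- model; tmp@params <- params; tmp@classes <- classes
    pv <- predictCells(tmp, tokensVal)
    valAcc <- mean(match(as.character(pv$labels), classes) == zVal)
    trainLoss <- epochLoss / n
    if (!is.finite(trainLoss)) {
      warning("non-finite loss; aborting with last finite checkpoint")
      break
    }
    history <- rbind(history, data.frame(epoch = ep, trainLoss = trainLoss,
                                         valAccuracy = valAcc))
    if (verbose)
      message(sprintf("epoch %d: train loss %.4f val acc %.3f", ep, trainLoss, valAcc))
    if (valAcc > best$acc) {
      best <- list(acc = valAcc, params = params, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  model@params <- best$params
  model@classes <- classes
  model@history <- history
  model
}

#' Predict cell types
#'
#' Batched inference: per-cell class probabilities from the fine-tuned
#' head (no dropout), argmax labels with ties broken by the lowest class
#' index. Results are identical whether cells are passed together or one
#' at a time.
#'
#' @param model a fine-tuned [ReformerModel-class].
#' @param tokens a [TokenizedCells-class] tokenized with the model's
#'   frozen binning scheme and vocabulary.
#' @return list with `probs` (cells x C matrix) and `labels` (factor).
#' @export
predictCells <- function(model, tokens) {
  cfg <- model@config
  bins <- if (methods::is(tokens, "TokenizedCells")) tokens@bins else tokens
  if (ncol(bins) != cfg@seqLen)
    stop(sprintf("tokens have %d genes but the model was trained on %d",
                 ncol(bins), cfg@seqLen), call. = FALSE)
  if (is.null(model@params$clsHead)) stop("model has no classification head",
                                          call. = FALSE)
  C <- length(model@params$clsHead$b3)
  probs <- matrix(0, nrow(bins), C)
  for (i in seq_len(nrow(bins))) {
    H <- encoderForward(bins[i, ], model@params, cfg, seed = 1L)$H
    probs[i, ] <- clsHeadForward(H, model@params, cfg)$probs
  }
  cls <- if (length(model@classes)) model@classes else as.character(seq_len(C))
  colnames(probs) <- cls
  rownames(probs) <- if (methods::is(tokens, "TokenizedCells")) tokens@cellIds
                     else rownames(bins)
  lab <- factor(cls[max.col(probs, ties.method = "first")], levels = cls)
  list(probs = probs, labels = lab)
}

#' Stratified k-fold cross-validation
#'
#' Folds are disjoint, exhaustive and stratified by class; each fold is
#' the test fold exactly once. Within each iteration a 10% slice of the
#' training cells is held out to monitor early stopping, the model is
#' fine-tuned (optionally from a shared pre-trained encoder) and the test
#' fold is scored. The summary reports mean and sample SD per metric.
#'
#' @param model a [ReformerModel-class] starting point (pre-trained or
#'   fresh); it is re-fine-tuned per fold from this state.
#' @param tokens a [TokenizedCells-class] for all cells.
#' @param classes labels aligned with the cells.
#' @param k number of folds (>= 2; published protocol 5).
#' @param seed integer seed (fold assignment + per-fold training).
#' @param ... passed to [finetuneReformer()].
#' @return list with `folds` (per-cell fold id), `reports` (per-fold
#'   [MetricsReport-class]) and `summary` (data.frame of mean/sd for
#'   accuracy and macro F1).
#' @export
crossValidate <- function(model, tokens, classes, k = 5L, seed = 2022L, ...) {
  n <- nrow(tokens@bins)
  if (k > n) stop("k exceeds the number of cells", call. = FALSE)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  classes <- as.character(classes)
  if (min(table(classes)) < k)
    warning("a class has fewer members than folds; stratification is best-effort")
  folds <- integer(n)
  withSeed(childSeed(seed, 500L), {
    off <- 0L
    for (cl in sort(unique(classes))) {
      idx <- which(classes == cl)
      # rotate the starting fold between classes so global fold sizes
      # stay balanced to within one cell
      folds[idx[sample.int(length(idx))]] <-
        ((seq_along(idx) - 1L + off) %% k) + 1L
      off <- (off + length(idx)) %% k
    }
  })
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    testIdx <- which(folds == f)
    trainIdx <- which(folds != f)
    # stratified 10% inner hold-out for early stopping; every class keeps
    # at least one training member
    innerVal <- withSeed(childSeed(seed, 600L + f), {
      unlist(lapply(sort(unique(classes[trainIdx])), function(cl) {
        ci <- trainIdx[classes[trainIdx] == cl]
        if (length(ci) < 2L) return(integer(0))
        sample(ci, max(1L, floor(length(ci) * 0.1)))
      }))
    })
    if (!length(innerVal)) innerVal <- trainIdx[1L]
    innerTrain <- setdiff(trainIdx, innerVal)
    fit <- finetuneReformer(model,
      subsetCells(tokens, innerTrain), classes[innerTrain],
      subsetCells(tokens, innerVal), classes[innerVal],
      seed = childSeed(seed, 700L + f), ...)
    pred <- predictCells(fit, subsetCells(tokens, testIdx))
    reports[[f]] <- evaluateClassifier(classes[testIdx],
                                       as.character(pred$labels),
                                       scores = pred$probs,
                                       classes = sort(unique(classes)))
  }
  accs <- vapply(reports, function(r) r@accuracy, numeric(1))
  f1s <- vapply(reports, function(r) r@macroF1, numeric(1))
  list(folds = folds, reports = reports,
       summary = data.frame(
         metric = c("accuracy", "macroF1"),
         mean = c(mean(accs), mean(f1s)),
         sd = c(stats::sd(accs), stats::sd(f1s))))
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint holding config, parameters, binning scheme and
#' class labels (RDS serialization).
#'
#' @param model a [ReformerModel-class].
#' @param path checkpoint file path.
#' @export
saveReformer <- function(model, path) {
  saveRDS(list(config = model@config, params = model@params,
               scheme = model@scheme, geneIds = model@geneIds,
               classes = model@classes, history = model@history), path)
  invisible(path)
}

#' @rdname saveReformer
#' @export
loadReformer <- function(path) {
  x <- readRDS(path)
  methods::new("ReformerModel", config = x$config, params = x$params,
               scheme = x$scheme, geneIds = x$geneIds, classes = x$classes,
               history = x$history)
}
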