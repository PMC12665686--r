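# Hand-written network engine: forward passes, exact backward passes, and
# the AdamW optimizer. Everything operates on one cell at a time (a cell is
# an L x d activation matrix); training loops batch by accumulating
# gradients. All caches are plain lists so the reversible stack can either
# keep them (stored-activation mode) or rebuild them on the backward pass
# (recompute mode).

# leaky ReLU for the feed-forward and head layers: the small negative
# slope keeps gradient flowing through units an early overshoot would
# otherwise kill permanently
gelu <- function(x) pmax(x, 0) + 0.01 * pmin(x, 0)
geluGrad <- function(x) (x > 0) + 0.01 * (x <= 0)

# column-wise scale/shift without sweep()'s aperm overhead
scaleCols <- function(x, g) x * rep(g, each = nrow(x))
addCols <- function(x, b) x + rep(b, each = nrow(x))

lnForward <- function(x, g, b, eps = 1e-5) {
  n <- nrow(x); d <- ncol(x)
  mu <- .rowMeans(x, n, d)
  xc <- x - mu
  v <- .rowMeans(xc * xc, n, d)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- addCols(scaleCols(xhat, g), b)
  list(y = y, xhat = xhat, inv = inv)
}

lnBackward <- function(dy, cache, g) {
  xhat <- cache$xhat
  n <- nrow(dy); d <- ncol(dy)
  dxhat <- scaleCols(dy, g)
  m1 <- .rowMeans(dxhat, n, d)
  m2 <- .rowMeans(dxhat * xhat, n, d)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dx = dx, dg = .colSums(dy * xhat, n, d), db = .colSums(dy, n, d))
}

headSlices <- function(d, nHeads) {
  dk <- d %/% nHeads
  lapply(seq_len(nHeads), function(h) ((h - 1L) * dk + 1L):(h * dk))
}

# ---- attention sublayer F(x) = MultiHeadLSHAttn(LN(x)) ----------------

# masks: optional precomputed list of per-head *additive* masks
# (0 allowed / -Inf blocked), reused on recompute so the discrete hash
# decisions are identical in both backward modes.
additiveMask <- function(logicalMask) {
  A <- matrix(0, nrow(logicalMask), ncol(logicalMask))
  A[!logicalMask] <- -Inf
  A
}

# chunk layout for the block-sparse path: positions sorted by (bucket,
# position), fixed-size chunks, chunk c attends chunks {c-1, c}
chunkLayout <- function(buckets, nBuckets) {
  n <- length(buckets)
  ord <- order(buckets, seq_len(n))
  m <- ceiling(n / nBuckets)
  nc <- ceiling(n / m)
  rows <- lapply(seq_len(nc), function(c) ((c - 1L) * m + 1L):min(c * m, n))
  cols <- lapply(seq_len(nc), function(c) {
    lo <- max(1L, (c - 2L) * m + 1L)
    lo:min(c * m, n)
  })
  list(ord = ord, rows = rows, cols = cols)
}

attnForward <- function(x, lp, cfg, layerSeed, masks = NULL) {
  ln <- lnForward(x, lp$ln1g, lp$ln1b)
  h <- ln$y
  Q <- h %*% lp$Wq
  V <- h %*% lp$Wv
  sl <- headSlices(cfg@dModel, cfg@nHeads)
  heads <- vector("list", cfg@nHeads)
  newMasks <- vector("list", cfg@nHeads)
  n <- nrow(x)
  O <- matrix(0, n, cfg@dModel)
  useBlocks <- cfg@attention == "lsh" && cfg@nBuckets > 1L &&
    cfg@nHashRounds == 1L && cfg@allowSelf
  for (hh in seq_len(cfg@nHeads)) {
    idx <- sl[[hh]]
    Qh <- Q[, idx, drop = FALSE]
    Vh <- V[, idx, drop = FALSE]
    r <- pmax(rowL2norm(Qh), 1e-12)
    Kh <- Qh / r
    dk <- length(idx)
    mask <- if (!is.null(masks)) masks[[hh]]
      else if (cfg@attention == "full" || cfg@nBuckets == 1L) NULL
      else if (useBlocks) {
        asg <- lshHash(Qh, cfg@nBuckets, 1L, childSeed(layerSeed, hh))
        c(list(blocked = TRUE), chunkLayout(asg[, 1L], cfg@nBuckets))
      } else {
        asg <- lshHash(Qh, cfg@nBuckets, cfg@nHashRounds,
                       childSeed(layerSeed, hh))
        additiveMask(bucketMask(asg, cfg@nBuckets, chunked = TRUE,
                                excludeSelf = !cfg@allowSelf))
      }
    if (is.list(mask)) {
      ord <- mask$ord
      Qs <- Qh[ord, , drop = FALSE]
      Ks <- Kh[ord, , drop = FALSE]
      Vs <- Vh[ord, , drop = FALSE]
      Os <- matrix(0, n, dk)
      Ablocks <- vector("list", length(mask$rows))
      for (cb in seq_along(mask$rows)) {
        ri <- mask$rows[[cb]]; ci <- mask$cols[[cb]]
        S <- tcrossprod(Qs[ri, , drop = FALSE], Ks[ci, , drop = FALSE]) / sqrt(dk)
        A <- softmaxRows(S)
        Os[ri, ] <- A %*% Vs[ci, , drop = FALSE]
        Ablocks[[cb]] <- A
      }
      O[ord, idx] <- Os
      heads[[hh]] <- list(Qh = Qh, Kh = Kh, Vh = Vh, r = r,
                          Ablocks = Ablocks, layout = mask)
    } else {
      S <- tcrossprod(Qh, Kh) / sqrt(dk)
      if (!is.null(mask)) S <- S + mask
      A <- softmaxRows(S)
      O[, idx] <- A %*% Vh
      heads[[hh]] <- list(Qh = Qh, Kh = Kh, Vh = Vh, A = A, r = r)
    }
    newMasks[[hh]] <- mask
  }
  out <- O %*% lp$Wo
  list(out = out,
       cache = list(ln = ln, h = h, O = O, heads = heads, masks = newMasks))
}

attnBackward <- function(dout, cache, lp, cfg) {
  h <- cache$h
  dWo <- crossprod(cache$O, dout)
  dO <- tcrossprod(dout, lp$Wo)
  sl <- headSlices(cfg@dModel, cfg@nHeads)
  dQ <- matrix(0, nrow(h), cfg@dModel)
  dV <- matrix(0, nrow(h), cfg@dModel)
  for (hh in seq_len(cfg@nHeads)) {
    idx <- sl[[hh]]
    hc <- cache$heads[[hh]]
    dk <- length(idx)
    dOh <- dO[, idx, drop = FALSE]
    if (!is.null(hc$layout)) {
      lay <- hc$layout
      ord <- lay$ord
      Qs <- hc$Qh[ord, , drop = FALSE]
      Ks <- hc$Kh[ord, , drop = FALSE]
      Vs <- hc$Vh[ord, , drop = FALSE]
      dOs <- dOh[ord, , drop = FALSE]
      dQs <- matrix(0, nrow(dOh), dk)
      dKs <- matrix(0, nrow(dOh), dk)
      dVs <- matrix(0, nrow(dOh), dk)
      for (cb in seq_along(lay$rows)) {
        ri <- lay$rows[[cb]]; ci <- lay$cols[[cb]]
        A <- hc$Ablocks[[cb]]
        dOb <- dOs[ri, , drop = FALSE]
        dA <- tcrossprod(dOb, Vs[ci, , drop = FALSE])
        dVs[ci, ] <- dVs[ci, ] + crossprod(A, dOb)
        dS <- A * (dA - rowSums(dA * A))
        dQs[ri, ] <- dQs[ri, ] + dS %*% Ks[ci, , drop = FALSE] / sqrt(dk)
        dKs[ci, ] <- dKs[ci, ] + crossprod(dS, Qs[ri, , drop = FALSE]) / sqrt(dk)
      }
      dQh <- matrix(0, nrow(dOh), dk); dQh[ord, ] <- dQs
      dKh <- matrix(0, nrow(dOh), dk); dKh[ord, ] <- dKs
      dVh <- matrix(0, nrow(dOh), dk); dVh[ord, ] <- dVs
    } else {
      dA <- tcrossprod(dOh, hc$Vh)
      dVh <- crossprod(hc$A, dOh)
      A <- hc$A
      dS <- A * (dA - rowSums(dA * A))
      dQh <- dS %*% hc$Kh / sqrt(dk)
      dKh <- crossprod(dS, hc$Qh) / sqrt(dk)
    }
    # K = Q / ||Q||: back through the row normalization
    dQh <- dQh + (dKh - hc$Kh * rowSums(hc$Kh * dKh)) / hc$r
    dQ[, idx] <- dQh
    dV[, idx] <- dVh
  }
  dWq <- crossprod(h, dQ)
  dWv <- crossprod(h, dV)
  dh <- tcrossprod(dQ, lp$Wq) + tcrossprod(dV, lp$Wv)
  lnb <- lnBackward(dh, cache$ln, lp$ln1g)
  list(dx = lnb$dx,
       grads = list(ln1g = lnb$dg, ln1b = lnb$db,
                    Wq = dWq, Wv = dWv, Wo = dWo))
}

# ---- feed-forward sublayer G(x) = FFN(LN(x)) --------------------------

ffnForward <- function(x, lp) {
  ln <- lnForward(x, lp$ln2g, lp$ln2b)
  pre <- addCols(ln$y %*% lp$W1, lp$b1)
  H1 <- gelu(pre)
  out <- addCols(H1 %*% lp$W2, lp$b2)
  list(out = out, cache = list(ln = ln, pre = pre, H1 = H1))
}

ffnBackward <- function(dout, cache, lp) {
  dW2 <- crossprod(cache$H1, dout)
  db2 <- .colSums(dout, nrow(dout), ncol(dout))
  dH1 <- tcrossprod(dout, lp$W2)
  dpre <- dH1 * geluGrad(cache$pre)
  dW1 <- crossprod(cache$ln$y, dpre)
  db1 <- .colSums(dpre, nrow(dpre), ncol(dpre))
  dln <- tcrossprod(dpre, lp$W1)
  lnb <- lnBackward(dln, cache$ln, lp$ln2g)
  list(dx = lnb$dx,
       grads = list(ln2g = lnb$dg, ln2b = lnb$db,
                    W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# ---- encoder: embeddings + reversible stack ---------------------------

embedForwardBins <- function(bins, params) {
  params$geneEmb + params$binEmb[bins + 1L, , drop = FALSE] + params$posEnc
}

# forward through the reversible stack
# storeActivations=TRUE keeps sublayer caches (baseline); FALSE keeps only
# (y1, y2) per layer plus the discrete attention masks, and the backward
# pass recomputes activations layer by layer (the Reformer memory scheme).
encoderForward <- function(bins, params, cfg, seed = 1L,
                           storeActivations = FALSE) {
  X <- embedForwardBins(bins, params)
  x1 <- X; x2 <- X
  layers <- vector("list", cfg@nLayers)
  for (l in seq_len(cfg@nLayers)) {
    lp <- params$layers[[l]]
    fa <- attnForward(x2, lp, cfg, layerSeed = childSeed(seed, l))
    y1 <- x1 + fa$out
    fg <- ffnForward(y1, lp)
    y2 <- x2 + fg$out
    layers[[l]] <- list(
      y1 = y1, y2 = y2, masks = fa$cache$masks,
      Fcache = if (storeActivations) fa$cache else NULL,
      Gcache = if (storeActivations) fg$cache else NULL)
    x1 <- y1; x2 <- y2
  }
  H <- (x1 + x2) / 2
  stopifnot_finite(H, "encoder output")
  list(H = H, cache = list(X = X, layers = layers, bins = bins,
                           stored = storeActivations))
}

# backward through the reversible stack; returns gradients for all encoder
# params (same structure as params) and nothing else.
encoderBackward <- function(dH, cache, params, cfg) {
  nL <- cfg@nLayers
  dy1 <- dH / 2
  dy2 <- dH / 2
  gradLayers <- vector("list", nL)
  if (nL > 0) {
    y1 <- cache$layers[[nL]]$y1
    y2 <- cache$layers[[nL]]$y2
    for (l in rev(seq_len(nL))) {
      lp <- params$layers[[l]]
      st <- cache$layers[[l]]
      if (cache$stored) {
        Gc <- st$Gcache
        Fc <- st$Fcache
        x2 <- if (l > 1L) cache$layers[[l - 1L]]$y2 else cache$X
        x1 <- if (l > 1L) cache$layers[[l - 1L]]$y1 else cache$X
      } else {
        fg <- ffnForward(y1, lp)
        Gc <- fg$cache
        x2 <- y2 - fg$out
        fa <- attnForward(x2, lp, cfg, layerSeed = 0L, masks = st$masks)
        Fc <- fa$cache
        x1 <- y1 - fa$out
      }
      gb <- ffnBackward(dy2, Gc, lp)
      dy1tot <- dy1 + gb$dx
      fb <- attnBackward(dy1tot, Fc, lp, cfg)
      dx1 <- dy1tot
      dx2 <- dy2 + fb$dx
      gradLayers[[l]] <- c(fb$grads, gb$grads)
      dy1 <- dx1; dy2 <- dx2
      y1 <- x1; y2 <- x2
    }
  }
  dX <- dy1 + dy2
  bins <- cache$bins
  dGene <- dX
  dBin <- rowsum(dX, group = bins, reorder = FALSE)
  dBinEmb <- matrix(0, nrow(params$binEmb), ncol(params$binEmb))
  dBinEmb[as.integer(rownames(dBin)) + 1L, ] <- dBin
  list(geneEmb = dGene, binEmb = dBinEmb, layers = gradLayers)
}

# ---- heads ------------------------------------------------------------

mlmHeadForward <- function(H, maskPos, params) {
  Z <- H[maskPos, , drop = FALSE]
  logits <- addCols(Z %*% params$mlmHead$Wr, params$mlmHead$br)
  P <- softmaxRows(logits)
  list(P = P, Z = Z)
}

mlmHeadBackward <- function(P, targets, Z, maskPos, Lseq, params, scale = 1) {
  dlogits <- P
  dlogits[cbind(seq_len(nrow(P)), targets + 1L)] <-
    dlogits[cbind(seq_len(nrow(P)), targets + 1L)] - 1
  dlogits <- dlogits * scale
  dWr <- crossprod(Z, dlogits)
  dbr <- colSums(dlogits)
  dZ <- tcrossprod(dlogits, params$mlmHead$Wr)
  dH <- matrix(0, Lseq, ncol(Z))
  dH[maskPos, ] <- dZ
  list(dH = dH, grads = list(Wr = dWr, br = dbr))
}

clsHeadForward <- function(H, params, cfg, dropMasks = NULL) {
  hp <- params$clsHead
  pre <- addCols(H %*% hp$Wc, hp$bc)
  Zc <- gelu(pre)
  # mean pooling integrates module-wide signal; max pooling catches
  # sparse markers that a mean over hundreds of genes would dilute
  amax <- max.col(t(Zc), ties.method = "first")
  cc <- ncol(Zc)
  rawPooled <- c(colMeans(Zc), Zc[cbind(amax, seq_len(cc))])
  # frozen per-channel standardization (fitted on training cells when the
  # head is attached): pooled channels are near-constant offsets plus a
  # small cell-specific part, and without centering/rescaling the head
  # sits in a long plateau predicting class priors before it can use
  # the signal
  pooled <- if (!is.null(params$clsNorm))
    (rawPooled - params$clsNorm$mu) / params$clsNorm$sd else rawPooled
  if (!is.null(dropMasks)) pooled <- pooled * dropMasks$p0
  a1 <- as.numeric(pooled %*% hp$W1) + hp$b1
  h1 <- gelu(a1)
  if (!is.null(dropMasks)) h1 <- h1 * dropMasks$p1
  a2 <- as.numeric(h1 %*% hp$W2) + hp$b2
  h2 <- gelu(a2)
  if (!is.null(dropMasks)) h2 <- h2 * dropMasks$p2
  logits <- as.numeric(h2 %*% hp$W3) + hp$b3
  probs <- {
    e <- exp(logits - max(logits)); e / sum(e)
  }
  list(probs = probs, logits = logits,
       cache = list(H = H, pre = pre, Zc = Zc, pooled = pooled,
                    amax = amax, a1 = a1, h1 = h1, a2 = a2, h2 = h2,
                    dropMasks = dropMasks))
}

clsHeadBackward <- function(dlogits, cache, params) {
  clsNorm <- params$clsNorm
  hp <- params$clsHead
  Lseq <- nrow(cache$H)
  dW3 <- outer(cache$h2, dlogits)
  db3 <- dlogits
  dh2 <- as.numeric(hp$W3 %*% dlogits)
  if (!is.null(cache$dropMasks)) dh2 <- dh2 * cache$dropMasks$p2
  da2 <- dh2 * geluGrad(cache$a2)
  dW2 <- outer(cache$h1, da2)
  db2 <- da2
  dh1 <- as.numeric(hp$W2 %*% da2)
  if (!is.null(cache$dropMasks)) dh1 <- dh1 * cache$dropMasks$p1
  da1 <- dh1 * geluGrad(cache$a1)
  dW1 <- outer(cache$pooled, da1)
  db1 <- da1
  dpooled <- as.numeric(hp$W1 %*% da1)
  if (!is.null(cache$dropMasks)) dpooled <- dpooled * cache$dropMasks$p0
  if (!is.null(clsNorm)) dpooled <- dpooled / clsNorm$sd
  cc <- ncol(cache$Zc)
  # mean part: every gene row receives d/L; max part: only the argmax row
  dZc <- matrix(dpooled[seq_len(cc)] / Lseq, Lseq, cc, byrow = TRUE)
  dZc[cbind(cache$amax, seq_len(cc))] <-
    dZc[cbind(cache$amax, seq_len(cc))] + dpooled[cc + seq_len(cc)]
  dpre <- dZc * geluGrad(cache$pre)
  dWc <- crossprod(cache$H, dpre)
  dbc <- colSums(dpre)
  dH <- tcrossprod(dpre, hp$Wc)
  list(dH = dH,
       grads = list(Wc = dWc, bc = dbc, W1 = dW1, b1 = db1,
                    W2 = dW2, b2 = db2, W3 = dW3, b3 = db3))
}

# raw pooled conv features of one cell (used to fit the frozen
# standardization of the classification head)
rawPooledFeatures <- function(params, cfg, bins, seed = 1L) {
  H <- encoderForward(bins, params, cfg, seed = seed)$H
  Zc <- gelu(addCols(H %*% params$clsHead$Wc, params$clsHead$bc))
  amax <- max.col(t(Zc), ties.method = "first")
  c(colMeans(Zc), Zc[cbind(amax, seq_len(ncol(Zc)))])
}

# ---- parameter initialization ----------------------------------------

xavier <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

initLayerParams <- function(cfg) {
  d <- cfg@dModel
  list(
    ln1g = rep(1, d), ln1b = rep(0, d),
    Wq = xavier(d, d), Wv = xavier(d, d), Wo = xavier(d, d),
    ln2g = rep(1, d), ln2b = rep(0, d),
    W1 = xavier(d, cfg@dFf), b1 = rep(0, cfg@dFf),
    W2 = xavier(cfg@dFf, d), b2 = rep(0, d)
  )
}
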