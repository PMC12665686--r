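#' Standard sinusoidal positional encoding
#'
#' `PE[pos, 2i+1] = sin(pos / 10000^(2i/d))`,
#' `PE[pos, 2i+2] = cos(pos / 10000^(2i/d))` over positions `0..L-1`.
#' Positions are the (fixed) gene order of the tokenized vocabulary.
#'
#' @param L sequence length (number of genes).
#' @param d embedding dimension.
#' @return L x d numeric matrix.
#' @export
sinusoidalEncoding <- function(L, d) {
  pos <- 0:(L - 1)
  pe <- matrix(0, L, d)
  i <- 0:(ceiling(d / 2) - 1)
  freq <- 1 / (10000^(2 * i / d))
  ang <- outer(pos, freq)
  pe[, seq(1, d, by = 2)] <- sin(ang)[, seq_along(seq(1, d, by = 2)), drop = FALSE]
  pe[, seq(2, d, by = 2)] <- cos(ang)[, seq_along(seq(2, d, by = 2)), drop = FALSE]
  pe
}

#' Scaled dot-product (full) attention
#'
#' `Attention(Q, K, V) = softmax(Q K^T / sqrt(d_k)) V`; every softmax row
#' sums to 1, so each output row is a convex combination of the rows of V.
#'
#' @param Q,K,V n x d_k numeric matrices.
#' @return n x ncol(V) numeric matrix.
#' @export
fullAttention <- function(Q, K, V) {
  stopifnot_finite(Q, "Q"); stopifnot_finite(K, "K"); stopifnot_finite(V, "V")
  if (nrow(Q) != nrow(K) || nrow(K) != nrow(V))
    stop("Q, K, V must have equal row counts", call. = FALSE)
  dk <- ncol(K)
  A <- softmaxRows(Q %*% t(K) / sqrt(dk))
  A %*% V
}

#' Angular LSH bucket assignment
#'
#' Random-rotation hashing: per round, project onto a seeded Gaussian
#' matrix R of shape `d_k x nBuckets/2` and take
#' `bucket = argmax [xR, -xR]`. Scale-invariant (v and 2v always collide);
#' antipodal vectors split for `nBuckets = 2`. A zero vector is assigned by
#' the argmax first-index convention. Deterministic given the seed.
#'
#' @param X n x d_k matrix of vectors to hash.
#' @param nBuckets even number of buckets (or 1 for the trivial single
#'   bucket).
#' @param nRounds independent hash rounds.
#' @param seed integer seed.
#' @return integer matrix n x nRounds of bucket ids in `1..nBuckets`.
#' @export
lshHash <- function(X, nBuckets, nRounds = 1L, seed = 1L) {
  n <- nrow(X)
  if (nBuckets == 1L) return(matrix(1L, n, nRounds))
  if (nBuckets %% 2L != 0L) stop("nBuckets must be 1 or even", call. = FALSE)
  out <- matrix(0L, n, nRounds)
  for (r in seq_len(nRounds)) {
    R <- withSeed(childSeed(seed, 101L, r), {
      G <- matrix(stats::rnorm(ncol(X) * nBuckets / 2), ncol(X), nBuckets / 2)
      # orthonormal columns when the dimension allows: projections of an
      # isotropic vector are then iid, so bucket occupancy is uniform
      if (ncol(X) >= nBuckets / 2) qr.Q(qr(G)) else G
    })
    P <- X %*% R
    out[, r] <- max.col(cbind(P, -P), ties.method = "first")
  }
  out
}

# Build the n x n logical attention mask from bucket assignments.
# chunked=TRUE follows the sort-by-bucket / chunk procedure (chunk size
# ceiling(n/nBuckets); each chunk attends within itself and to its
# predecessor); chunked=FALSE is the pure same-bucket rule P_i = {j :
# h(q_i) = h(k_j)}. Rounds are unioned. excludeSelf removes the diagonal
# except where a position would otherwise attend to nothing.
bucketMask <- function(assignment, nBuckets, chunked = TRUE, excludeSelf = FALSE) {
  n <- nrow(assignment)
  M <- matrix(FALSE, n, n)
  for (r in seq_len(ncol(assignment))) {
    b <- assignment[, r]
    if (chunked) {
      ord <- order(b, seq_len(n))
      m <- ceiling(n / nBuckets)
      chunk <- integer(n)
      chunk[ord] <- ((seq_len(n) - 1L) %/% m) + 1L
      nc <- max(chunk)
      for (cid in seq_len(nc)) {
        rows <- which(chunk == cid)
        cols <- which(chunk == cid | chunk == cid - 1L)
        M[rows, cols] <- TRUE
      }
    } else {
      for (bb in unique(b)) {
        idx <- which(b == bb)
        M[idx, idx] <- TRUE
      }
    }
  }
  if (excludeSelf) {
    diagIdx <- cbind(seq_len(n), seq_len(n))
    keep <- rowSums(M) - M[diagIdx] == 0  # sole member: keep self
    M[diagIdx] <- keep
  }
  M
}

maskedAttention <- function(Q, K, V, mask) {
  dk <- ncol(K)
  S <- Q %*% t(K) / sqrt(dk)
  if (!is.null(mask)) S[!mask] <- -Inf
  softmaxRows(S) %*% V
}

#' LSH attention
#'
#' Shared-QK attention restricted to hash buckets: keys are the
#' row-normalized queries (the Reformer regime, required so that queries
#' and keys land in consistent buckets), and position i attends to the
#' candidate set P_i derived from the hash — either the pure same-bucket
#' rule of the bucket equation, or the sort-and-chunk procedure (chunk
#' size `ceiling(n/nBuckets)`, each chunk also attending to its
#' predecessor) used inside the encoder. Candidate sets are unioned over
#' hash rounds, then a single softmax is taken over each row's candidates.
#' With `nBuckets = 1` every position is a candidate of every other and
#' the result equals [fullAttention()] exactly.
#'
#' Evaluation is a masked dense softmax: mathematically identical to the
#' bucketed sparse kernel at any size this package targets.
#'
#' @param Q n x d_k query matrix (keys are derived from it).
#' @param V n x d_k value matrix.
#' @param nBuckets number of hash buckets (1 or even).
#' @param nRounds hash rounds (candidate sets are unioned).
#' @param seed hashing seed.
#' @param assignment optional externally fixed n x rounds bucket-id matrix;
#'   when supplied, hashing is skipped and the pure same-bucket rule is
#'   used unless `chunked = TRUE` is given explicitly.
#' @param chunked use the sort-and-chunk candidate sets (default TRUE when
#'   hashing internally, FALSE for an external `assignment`).
#' @param allowSelf may a position attend to itself (default TRUE;
#'   FALSE reproduces the Reformer exclude-self convention, keeping the
#'   diagonal only where a position would otherwise be isolated).
#' @return n x d_k output matrix.
#' @export
lshAttention <- function(Q, V, nBuckets = 64L, nRounds = 1L, seed = 1L,
                         assignment = NULL, chunked = is.null(assignment),
                         allowSelf = TRUE) {
  stopifnot_finite(Q, "Q"); stopifnot_finite(V, "V")
  n <- nrow(Q)
  K <- Q / pmax(rowL2norm(Q), 1e-12)
  if (is.null(assignment)) {
    assignment <- lshHash(Q, nBuckets, nRounds, seed)
  } else {
    assignment <- as.matrix(assignment)
    if (nrow(assignment) != n)
      stop("assignment length does not match number of rows", call. = FALSE)
  }
  mask <- if (all(assignment == assignment[1, 1]) && !chunked) NULL
          else bucketMask(assignment, nBuckets, chunked = chunked,
                          excludeSelf = !allowSelf)
  if (nBuckets == 1L && allowSelf) mask <- NULL
  maskedAttention(Q, K, V, mask)
}

#' Reversible residual coupling
#'
#' `y1 = x1 + F(x2); y2 = x2 + G(y1)`. The inverse recomputes the inputs
#' from the outputs without stored activations:
#' `x2 = y2 - G(y1); x1 = y1 - F(x2)`. This is the memory device that lets
#' a deep encoder train without keeping per-layer activations.
#'
#' @param x1,x2 equal-shape numeric matrices (the two half-states).
#' @param F,G functions mapping a half-state to an equal-shape matrix.
#' @return list with elements `y1`, `y2` (forward) or `x1`, `x2` (inverse).
#' @export
reversibleForward <- function(x1, x2, F, G) {
  if (!identical(dim(x1), dim(x2)))
    stop("x1 and x2 must have identical shapes", call. = FALSE)
  y1 <- x1 + F(x2)
  y2 <- x2 + G(y1)
  list(y1 = y1, y2 = y2)
}

#' @rdname reversibleForward
#' @param y1,y2 outputs of [reversibleForward()].
#' @export
reversibleInverse <- function(y1, y2, F, G) {
  if (!identical(dim(y1), dim(y2)))
    stop("y1 and y2 must have identical shapes", call. = FALSE)
  x2 <- y2 - G(y1)
  x1 <- y1 - F(x2)
  list(x1 = x1, x2 = x2)
}
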