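# internal helpers

# run expr with a temporary RNG state seeded by `seed`; global stream untouched
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# derive a child seed (kept well below 2^31) from a base seed and tags
childSeed <- function(seed, ...) {
  tags <- c(...)
  s <- as.double(seed) %% 2147483647
  for (t in tags) s <- (s * 69069 + as.double(t) * 9973 + 1) %% 2147483647
  as.integer(s)
}

softmaxRows <- function(S) {
  # rowwise max via max.col (C code); guard rows that are entirely -Inf
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  m[!is.finite(m)] <- 0
  E <- exp(S - m)
  E / pmax(rowSums(E), .Machine$double.xmin)
}

rowL2norm <- function(X) sqrt(rowSums(X * X))

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(TRUE)
}

# recursive map over a nested list of numeric arrays
paramMap <- function(p, f) {
  if (is.list(p)) lapply(p, paramMap, f = f) else f(p)
}

# recursive binary zip over two nested lists with identical structure
paramZip <- function(a, b, f) {
  if (is.list(a)) mapply(paramZip, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
  else f(a, b)
}

paramSumSq <- function(p) {
  if (is.list(p)) sum(vapply(p, paramSumSq, numeric(1))) else sum(p^2)
}

# zero-filled copy with identical structure
paramZero <- function(p) paramMap(p, function(x) x * 0)
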