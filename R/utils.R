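# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# round() uses round-half-to-even; proportional thresholding needs a fixed
# half-away-from-zero rule so edge counts are reproducible across platforms.
roundHalfUp <- function(x) floor(x + 0.5)

# Derive a per-analysis RNG seed from the global analysis seed and a counter,
# keeping the result a valid positive 32-bit integer.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483646) + 1L
}

# Upper-triangle edge list of a square matrix, ordered by descending weight
# with ties broken by ascending (row, column). Shared by the thresholding
# operation and the fast sweep path so both use identical tie-breaking.
orderedEdgeList <- function(w) {
  n <- nrow(w)
  ut <- which(upper.tri(w))
  i <- ((ut - 1L) %% n) + 1L
  j <- ((ut - 1L) %/% n) + 1L
  wv <- w[ut]
  ord <- order(-wv, i, j)
  list(i = i[ord], j = j[ord], w = wv[ord])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
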