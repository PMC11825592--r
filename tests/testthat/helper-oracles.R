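# Independent oracles and small fixture builders used across the suite.

# Wrap a binary adjacency matrix as a ThresholdedNetwork.
tnFromAdj <- function(adj, labels = NULL) {
  n <- nrow(adj)
  labels <- labels %||% sprintf("n%02d", seq_len(n))
  dimnames(adj) <- list(labels, labels)
  new("ThresholdedNetwork", labels = labels, adjacency = adj,
      densityPercent = as.integer(round(100 * sum(adj) / (n * (n - 1)))),
      edgeCount = as.integer(sum(adj) / 2), densityAchieved = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Symmetric binary Erdos-Renyi adjacency.
randomAdjacency <- function(n, p) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# Brute-force betweenness: enumerate every shortest path between every
# unordered node pair by exhaustive depth-first search (no Brandes
# accumulation anywhere). Only feasible for small n.
bruteForceBetweenness <- function(adj) {
  n <- nrow(adj)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq.int(s + 1, n)) {
      best <- Inf
      paths <- list()
      dfs <- function(v, visited, len) {
        if (v == t) {
          if (len < best) {
            best <<- len
            paths <<- list()
          }
          if (len == best) paths[[length(paths) + 1L]] <<- visited
          return(invisible())
        }
        if (len >= best) return(invisible())
        for (u in which(adj[v, ] == 1)) {
          if (!(u %in% visited)) dfs(u, c(visited, u), len + 1L)
        }
      }
      dfs(s, s, 0L)
      if (!length(paths)) next
      inner <- unlist(lapply(paths, function(p) p[-c(1L, length(p))]))
      if (length(inner)) {
        tb <- table(inner)
        ix <- as.integer(names(tb))
        bc[ix] <- bc[ix] + as.numeric(tb) / length(paths)
      }
    }
  }
  bc
}

# Exhaustive two-sample permutation p-value by explicit enumeration of all
# choose(nA + nB, nA) label assignments of the pooled-variance t.
exhaustivePermP <- function(a, b) {
  x <- c(a, b)
  n <- length(x)
  nA <- length(a)
  tfun <- function(ii) {
    aa <- x[ii]; bb <- x[-ii]
    sp2 <- ((length(aa) - 1) * var(aa) + (length(bb) - 1) * var(bb)) / (n - 2)
    (mean(aa) - mean(bb)) / sqrt(sp2 * (1 / length(aa) + 1 / length(bb)))
  }
  tObs <- tfun(seq_len(nA))
  tPerm <- apply(combn(n, nA), 2L, tfun)
  mean(abs(tPerm) >= abs(tObs) - 1e-12)
}

# Tiny default cohort for pipeline tests: small networks, strong effect.
smallCohort <- function(seed = 11L, d = 1.2, nNodes = 24L, nA = 12L,
                        nB = 9L, nU = 1L) {
  generateCohort(cohortSpec(nNodes = nNodes, nGroupA = nA, nGroupB = nB,
                            nUnclassified = nU, degreeEffectD = d,
                            seed = seed))
}

smallConfig <- function(seed = 11L, nPerm = 500L) {
  analysisConfig(nPermutations = nPerm, seed = seed)
}
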