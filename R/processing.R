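#' Normalize a connectome by its waytotals
#'
#' Divides each row of the raw streamline-count matrix by the seed
#' region's waytotal (the total number of streamlines propagated from
#' that region), converting counts to seeding-independent connection
#' strengths. This is step (i) of matrix processing; the result is still
#' asymmetric.
#'
#' @param x a [Connectome-class] object.
#' @return Square nonnegative numeric matrix of normalized strengths,
#'   zero diagonal, same dimnames as the input counts.
#' @examples
#' m <- matrix(c(0, 10, 20, 5, 0, 5, 2, 8, 0), 3, 3, byrow = TRUE)
#' cn <- Connectome(m, waytotals = c(100, 50, 10))
#' normalizeByWaytotal(cn)
#' @seealso [symmetrize()], [processConnectome()]
#' @export
normalizeByWaytotal <- function(x) {
  stopifnot(is(x, "Connectome"))
  validObject(x)
  x@counts / x@waytotals
}

#' Symmetrize a connectivity matrix
#'
#' Renders an asymmetric normalized matrix symmetric by averaging each
#' pair of directed entries: `out[i,j] = (w[i,j] + w[j,i]) / 2`. This is
#' step (ii) of matrix processing.
#'
#' @param w square nonnegative numeric matrix with zero diagonal.
#' @param labels optional node labels (default: dimnames of `w`).
#' @return A [ProcessedNetwork-class] object.
#' @examples
#' symmetrize(matrix(c(0, 4, 2, 0), 2, 2))
#' @export
symmetrize <- function(w, labels = NULL) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) stop("input matrix must be square")
  if (any(!is.finite(w)) || any(w < 0))
    stop("input matrix must be finite and nonnegative")
  if (any(diag(w) != 0)) stop("input matrix must have a zero diagonal")
  ProcessedNetwork((w + t(w)) / 2, labels = labels)
}

#' Normalize and symmetrize in one step
#'
#' @param x a [Connectome-class] object.
#' @return A [ProcessedNetwork-class] object.
#' @export
processConnectome <- function(x) {
  symmetrize(normalizeByWaytotal(x), labels = x@labels)
}

#' Threshold a network to a proportional density
#'
#' Keeps the `k = round(density * n(n-1)/2)` strongest undirected
#' connections (round half away from zero) and binarizes them, step
#' (iii) of matrix processing. Ties at the cutoff weight are broken
#' deterministically by ascending (row, column) index. If the network
#' has fewer than `k` positive weights, all positive connections are
#' kept and the `densityAchieved` flag is set to `FALSE`.
#'
#' @param x a [ProcessedNetwork-class] object.
#' @param density target network density as a fraction in (0, 1].
#' @return A [ThresholdedNetwork-class] object.
#' @examples
#' set.seed(1)
#' w <- matrix(runif(25), 5, 5); w <- (w + t(w)) / 2; diag(w) <- 0
#' thresholdToDensity(ProcessedNetwork(w), 0.3)
#' @seealso [densitySweep()]
#' @export
thresholdToDensity <- function(x, density) {
  stopifnot(is(x, "ProcessedNetwork"))
  if (!is.numeric(density) || length(density) != 1L ||
      density <= 0 || density > 1)
    stop("density must be a single value in (0, 1]")
  n <- length(x@labels)
  k <- as.integer(roundHalfUp(density * n * (n - 1) / 2))
  el <- orderedEdgeList(x@weights)
  pos <- sum(el$w > 0)
  achieved <- pos >= k
  keep <- seq_len(min(k, pos))
  a <- matrix(0, n, n, dimnames = list(x@labels, x@labels))
  a[cbind(el$i[keep], el$j[keep])] <- 1
  a[cbind(el$j[keep], el$i[keep])] <- 1
  new("ThresholdedNetwork", labels = x@labels, adjacency = a,
      densityPercent = as.integer(roundHalfUp(density * 100)),
      edgeCount = length(keep), densityAchieved = achieved)
}

#' Threshold a network across a sweep of densities
#'
#' Produces one [ThresholdedNetwork-class] per density in the sweep
#' `{low, low + step, ..., high}` (integer percents; the default
#' 20--40% in 1% steps yields 21 networks). Densities are handled as
#' exact integer percents to avoid floating-point drift in the sweep.
#'
#' @param x a [ProcessedNetwork-class] object.
#' @param low,high,step sweep bounds and step size in integer percent.
#' @return List of [ThresholdedNetwork-class] objects, named by percent.
#' @examples
#' set.seed(1)
#' w <- matrix(runif(64), 8, 8); w <- (w + t(w)) / 2; diag(w) <- 0
#' length(densitySweep(ProcessedNetwork(w)))  # 21
#' @export
densitySweep <- function(x, low = 20L, high = 40L, step = 1L) {
  pct <- sweepPercents(low, high, step)
  out <- lapply(pct, function(p) thresholdToDensity(x, p / 100))
  names(out) <- paste0(pct, "%")
  out
}

# Validated integer-percent sequence for the density sweep.
sweepPercents <- function(low, high, step) {
  if (any(c(low, high, step) != as.integer(c(low, high, step))))
    stop("density sweep bounds and step must be integer percents")
  low <- as.integer(low); high <- as.integer(high); step <- as.integer(step)
  if (low < 1L || high > 100L || low > high || step < 1L)
    stop("invalid density sweep: need 1 <= low <= high <= 100 and step >= 1")
  seq.int(low, high, by = step)
}

#' Test whether a thresholded network is fragmented
#'
#' A network is fragmented when its binary graph has more than one
#' connected component (isolated nodes count as components). Path-based
#' centrality metrics are degenerate on fragmented graphs, which is the
#' rationale for the 20% lower bound of the default density sweep.
#'
#' @param x a [ThresholdedNetwork-class] object.
#' @return `TRUE` if the graph has more than one connected component.
#' @examples
#' two_triangles <- matrix(0, 6, 6)
#' two_triangles[cbind(c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4))] <- 1
#' two_triangles <- pmax(two_triangles, t(two_triangles))
#' tn <- new("ThresholdedNetwork", labels = letters[1:6],
#'           adjacency = two_triangles, densityPercent = 20L,
#'           edgeCount = 6L, densityAchieved = TRUE)
#' isFragmented(tn)  # TRUE
#' @export
setMethod("isFragmented", "ThresholdedNetwork", function(x) {
  g <- igraph::graph_from_adjacency_matrix(x@adjacency, mode = "undirected")
  igraph::components(g)$no > 1L
})
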