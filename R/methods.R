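#' Construct a raw connectome
#'
#' @param counts square nonnegative numeric matrix of streamline counts
#'   with zero diagonal. Dimnames, if present, supply the labels.
#' @param waytotals positive numeric vector of per-region waytotals; a
#'   single value is recycled.
#' @param labels optional character vector of parcel names; defaults to
#'   the row names of `counts` or `node001`, `node002`, ...
#' @param subjectID subject identifier.
#' @return A [Connectome-class] object.
#' @examples
#' m <- matrix(c(0, 10, 20, 5, 0, 5, 2, 8, 0), 3, 3, byrow = TRUE)
#' Connectome(m, waytotals = c(100, 50, 10))
#' @export
Connectome <- function(counts, waytotals, labels = NULL, subjectID = "subject") {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop("counts must be a square matrix, got ", nrow(counts), " x ",
         ncol(counts))
  if (is.null(labels)) {
    labels <- rownames(counts)
    if (is.null(labels)) labels <- sprintf("node%03d", seq_len(nrow(counts)))
  }
  if (length(waytotals) == 1L) waytotals <- rep(waytotals, nrow(counts))
  dimnames(counts) <- list(labels, labels)
  names(waytotals) <- labels
  new("Connectome", labels = as.character(labels), counts = counts,
      waytotals = as.numeric(waytotals), subjectID = as.character(subjectID))
}

#' Construct a processed (normalized, symmetric) network
#'
#' Usually produced by [processConnectome()]; the constructor is exposed
#' for assembling networks from external sources.
#'
#' @param weights symmetric nonnegative matrix, zero diagonal.
#' @param labels optional parcel names (default: dimnames or generated).
#' @return A [ProcessedNetwork-class] object.
#' @export
ProcessedNetwork <- function(weights, labels = NULL) {
  weights <- as.matrix(weights)
  if (is.null(labels)) {
    labels <- rownames(weights)
    if (is.null(labels)) labels <- sprintf("node%03d", seq_len(nrow(weights)))
  }
  dimnames(weights) <- list(labels, labels)
  new("ProcessedNetwork", labels = as.character(labels), weights = weights)
}

## ---- accessors ------------------------------------------------------------

#' @rdname netcentral-accessors
#' @export
setMethod("nodeLabels", "Connectome", function(x) x@labels)
#' @rdname netcentral-accessors
#' @export
setMethod("nodeLabels", "ProcessedNetwork", function(x) x@labels)
#' @rdname netcentral-accessors
#' @export
setMethod("nodeLabels", "ThresholdedNetwork", function(x) x@labels)
#' @rdname netcentral-accessors
#' @export
setMethod("nodeLabels", "CentralityProfile", function(x) x@labels)
#' @rdname netcentral-accessors
#' @export
setMethod("nodeLabels", "IntegratedCentrality", function(x) x@labels)

#' @rdname netcentral-accessors
#' @export
setMethod("nNodes", "Connectome", function(x) length(x@labels))
#' @rdname netcentral-accessors
#' @export
setMethod("nNodes", "ProcessedNetwork", function(x) length(x@labels))
#' @rdname netcentral-accessors
#' @export
setMethod("nNodes", "ThresholdedNetwork", function(x) length(x@labels))

#' @rdname netcentral-accessors
#' @export
setMethod("streamlineCounts", "Connectome", function(x) x@counts)

#' @rdname netcentral-accessors
#' @export
setMethod("wayTotals", "Connectome", function(x) x@waytotals)

#' @rdname netcentral-accessors
#' @export
setMethod("subjectID", "Connectome", function(x) x@subjectID)

#' @rdname netcentral-accessors
#' @export
setMethod("edgeWeights", "ProcessedNetwork", function(x) x@weights)

#' @rdname netcentral-accessors
#' @export
setMethod("adjacency", "ThresholdedNetwork", function(x) x@adjacency)

#' @rdname netcentral-accessors
#' @export
setMethod("densityPercent", "ThresholdedNetwork", function(x) x@densityPercent)

#' @rdname netcentral-accessors
#' @export
setMethod("edgeCount", "ThresholdedNetwork", function(x) x@edgeCount)

#' @rdname netcentral-accessors
#' @export
setMethod("metricName", "CentralityProfile", function(x) x@metricName)
#' @rdname netcentral-accessors
#' @export
setMethod("metricName", "IntegratedCentrality", function(x) x@metricName)

#' @rdname netcentral-accessors
#' @export
setMethod("metricValues", "CentralityProfile", function(x) x@values)
#' @rdname netcentral-accessors
#' @export
setMethod("metricValues", "IntegratedCentrality", function(x) x@values)

#' @rdname netcentral-accessors
#' @export
setMethod("densities", "CentralityProfile", function(x) x@densities)

#' @rdname netcentral-accessors
#' @export
setMethod("connectomes", "SyntheticCohort", function(x) x@connectomes)

#' @rdname netcentral-accessors
#' @export
setMethod("clinicalTable", "SyntheticCohort", function(x) x@clinical)

#' @rdname netcentral-accessors
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)

## ---- show -----------------------------------------------------------------

setMethod("show", "Connectome", function(object) {
  n <- length(object@labels)
  cat("Connectome object\n")
  cat("  subject:", object@subjectID, "\n")
  cat("  nodes:  ", n, "\n")
  off <- object@counts[row(object@counts) != col(object@counts)]
  cat(sprintf("  nonzero off-diagonal fraction: %.3f\n", mean(off > 0)))
  cat(sprintf("  total streamline count: %s\n",
              format(sum(object@counts), big.mark = ",")))
})

setMethod("show", "ProcessedNetwork", function(object) {
  cat("ProcessedNetwork object\n")
  cat("  nodes:", length(object@labels), "\n")
  w <- object@weights[upper.tri(object@weights)]
  cat(sprintf("  positive connections: %d of %d possible\n",
              sum(w > 0), length(w)))
})

setMethod("show", "ThresholdedNetwork", function(object) {
  cat("ThresholdedNetwork object\n")
  cat("  nodes:", length(object@labels),
      " density:", object@densityPercent, "%",
      " edges:", object@edgeCount, "\n")
  if (!object@densityAchieved)
    cat("  note: fewer positive weights than requested density; achieved",
        "density is lower\n")
})

setMethod("show", "CentralityProfile", function(object) {
  cat("CentralityProfile object\n")
  cat("  metric:", object@metricName, "\n")
  cat("  densities:", length(object@densities),
      sprintf("(%d%%-%d%%)", min(object@densities), max(object@densities)),
      " nodes:", length(object@labels), "\n")
})

setMethod("show", "IntegratedCentrality", function(object) {
  cat("IntegratedCentrality object\n")
  cat("  metric:", object@metricName, " nodes:", length(object@labels), "\n")
  top <- head(sort(object@values, decreasing = TRUE), 3L)
  cat("  top nodes:", paste(sprintf("%s (%.4g)", names(top), top),
                            collapse = ", "), "\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  cl <- object@clinical
  cat("SyntheticCohort object\n")
  cat("  subjects:", nrow(cl),
      sprintf("(%d drug-resistant, %d drug-sensitive, %d unclassified)\n",
              sum(cl$drug_resistant %in% TRUE),
              sum(cl$drug_resistant %in% FALSE),
              sum(is.na(cl$drug_resistant))))
  cat("  nodes:", length(object@connectomes[[1]]@labels),
      " effect node:", object@truth$effectNode, "\n")
})
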