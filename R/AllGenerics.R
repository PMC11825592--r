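#' @name netcentral-accessors
#' @title Accessors for netcentral classes
#'
#' @description Accessor generics for the container classes:
#' `nodeLabels()` returns the parcel names, `nNodes()` their number,
#' `streamlineCounts()` the raw count matrix, `wayTotals()` the
#' per-region waytotals, `subjectID()` the subject identifier,
#' `edgeWeights()` the normalized symmetric weight matrix,
#' `adjacency()` the binary matrix of a thresholded network,
#' `densityPercent()` and `edgeCount()` its density and edge number,
#' `metricName()` / `metricValues()` / `densities()` the contents of
#' centrality containers, and `connectomes()` / `clinicalTable()` /
#' `cohortTruth()` the parts of a synthetic cohort.
#'
#' @param x an object of the appropriate class.
#' @return The slot contents; see the class documentation pages.
#' @examples
#' cn <- Connectome(matrix(c(0, 2, 3, 0), 2, 2), waytotals = c(10, 10))
#' nodeLabels(cn)
#' wayTotals(cn)
NULL

#' @rdname netcentral-accessors
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname netcentral-accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname netcentral-accessors
#' @export
setGeneric("streamlineCounts", function(x) standardGeneric("streamlineCounts"))

#' @rdname netcentral-accessors
#' @export
setGeneric("wayTotals", function(x) standardGeneric("wayTotals"))

#' @rdname netcentral-accessors
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname netcentral-accessors
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname netcentral-accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname netcentral-accessors
#' @export
setGeneric("densityPercent", function(x) standardGeneric("densityPercent"))

#' @rdname netcentral-accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))

#' @rdname netcentral-accessors
#' @export
setGeneric("metricName", function(x) standardGeneric("metricName"))

#' @rdname netcentral-accessors
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' @rdname netcentral-accessors
#' @export
setGeneric("densities", function(x) standardGeneric("densities"))

#' @rdname netcentral-accessors
#' @export
setGeneric("connectomes", function(x) standardGeneric("connectomes"))

#' @rdname netcentral-accessors
#' @export
setGeneric("clinicalTable", function(x) standardGeneric("clinicalTable"))

#' @rdname netcentral-accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname isFragmented
#' @export
setGeneric("isFragmented", function(x) standardGeneric("isFragmented"))

#' @rdname nodeDegree
#' @export
setGeneric("nodeDegree", function(x) standardGeneric("nodeDegree"))

#' @rdname betweennessCentrality
#' @export
setGeneric("betweennessCentrality",
  function(x) standardGeneric("betweennessCentrality"))

#' @rdname integrateAcrossDensities
#' @export
setGeneric("integrateAcrossDensities",
  function(x) standardGeneric("integrateAcrossDensities"))
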