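#' @import methods
NULL

#' Raw streamline-count connectome
#'
#' Container for the raw output of probabilistic tractography on one
#' subject: a square, generally asymmetric matrix of streamline counts
#' between labelled grey-matter parcels, together with the per-region
#' waytotals (total streamlines successfully propagated from each seed
#' region) used later for normalization.
#'
#' @slot labels character vector of unique parcel names, one per node.
#' @slot counts numeric matrix of nonnegative streamline counts with a
#'   zero diagonal; rows index seed regions, columns target regions.
#' @slot waytotals positive numeric vector, one waytotal per region.
#' @slot subjectID scalar character subject identifier.
#'
#' @seealso [Connectome()] for the constructor,
#'   [normalizeByWaytotal()], [subjectCentrality()]
#' @export
setClass("Connectome",
  slots = c(
    labels = "character",
    counts = "matrix",
    waytotals = "numeric",
    subjectID = "character"
  )
)

setValidity("Connectome", function(object) {
  msg <- character()
  n <- length(object@labels)
  cn <- object@counts
  if (anyDuplicated(object@labels))
    msg <- c(msg, "node labels must be unique")
  if (!is.numeric(cn) || nrow(cn) != ncol(cn))
    msg <- c(msg, "counts must be a square numeric matrix")
  else {
    if (nrow(cn) != n)
      msg <- c(msg, "dimension of counts does not match number of labels")
    if (any(!is.finite(cn)) || any(cn < 0))
      msg <- c(msg, "counts must be finite and nonnegative")
    else if (any(diag(cn) != 0))
      msg <- c(msg, "diagonal of counts must be zero")
  }
  if (length(object@waytotals) != n)
    msg <- c(msg, "need one waytotal per region")
  else if (any(!is.finite(object@waytotals)) || any(object@waytotals <= 0))
    msg <- c(msg, "waytotals must be finite and strictly positive")
  if (length(object@subjectID) != 1L)
    msg <- c(msg, "subjectID must be a single string")
  if (length(msg)) msg else TRUE
})

#' Normalized, symmetric connectivity network
#'
#' A connectome after waytotal normalization and symmetrization: a
#' symmetric nonnegative weight matrix (unitless connection strengths)
#' with zero diagonal, ready for proportional density thresholding.
#'
#' @slot labels character vector of parcel names.
#' @slot weights symmetric nonnegative numeric matrix, zero diagonal.
#'
#' @seealso [processConnectome()], [thresholdToDensity()]
#' @export
setClass("ProcessedNetwork",
  slots = c(labels = "character", weights = "matrix")
)

setValidity("ProcessedNetwork", function(object) {
  msg <- character()
  w <- object@weights
  if (anyDuplicated(object@labels))
    msg <- c(msg, "node labels must be unique")
  if (!is.numeric(w) || nrow(w) != ncol(w))
    msg <- c(msg, "weights must be a square numeric matrix")
  else {
    if (nrow(w) != length(object@labels))
      msg <- c(msg, "dimension of weights does not match number of labels")
    if (any(!is.finite(w)) || any(w < 0))
      msg <- c(msg, "weights must be finite and nonnegative")
    else {
      if (!isTRUE(all.equal(w, t(w), tolerance = 0)) && !identical(w, t(w)))
        msg <- c(msg, "weights must be exactly symmetric")
      if (any(diag(w) != 0))
        msg <- c(msg, "diagonal of weights must be zero")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Binary network at a fixed proportional density
#'
#' The result of keeping the k strongest undirected connections of a
#' [ProcessedNetwork-class], where k is determined by the requested
#' network density (the fraction of all possible node pairs retained).
#'
#' @slot labels character vector of parcel names.
#' @slot adjacency symmetric binary (0/1) matrix, zero diagonal.
#' @slot densityPercent integer, the requested density in percent.
#' @slot edgeCount integer, number of undirected edges retained.
#' @slot densityAchieved logical; `FALSE` when fewer positive weights
#'   existed than the density asked for, so the achieved density is
#'   below the request.
#'
#' @seealso [thresholdToDensity()], [densitySweep()], [isFragmented()]
#' @export
setClass("ThresholdedNetwork",
  slots = c(
    labels = "character",
    adjacency = "matrix",
    densityPercent = "integer",
    edgeCount = "integer",
    densityAchieved = "logical"
  )
)

setValidity("ThresholdedNetwork", function(object) {
  msg <- character()
  a <- object@adjacency
  if (!is.numeric(a) || nrow(a) != ncol(a))
    msg <- c(msg, "adjacency must be a square numeric matrix")
  else {
    if (nrow(a) != length(object@labels))
      msg <- c(msg, "dimension of adjacency does not match number of labels")
    if (!all(a %in% c(0, 1)))
      msg <- c(msg, "adjacency must be binary")
    else {
      if (!identical(a, t(a)))
        msg <- c(msg, "adjacency must be symmetric")
      if (any(diag(a) != 0))
        msg <- c(msg, "diagonal of adjacency must be zero")
      if (sum(a) / 2 != object@edgeCount)
        msg <- c(msg, "edgeCount does not match adjacency")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-density centrality values for one subject and one metric
#'
#' A (densities x nodes) matrix holding one centrality metric evaluated
#' at every network density of the sweep, e.g. 21 densities x 82 regions
#' for the default 20--40% sweep on an 82-node parcellation.
#'
#' @slot metricName `"degree"` or `"betweenness"`.
#' @slot values numeric matrix, rows = densities, columns = nodes.
#' @slot densities integer vector of density percents, strictly increasing.
#' @slot labels character vector of parcel names (column order).
#'
#' @seealso [centralityProfile()], [integrateAcrossDensities()]
#' @export
setClass("CentralityProfile",
  slots = c(
    metricName = "character",
    values = "matrix",
    densities = "integer",
    labels = "character"
  )
)

setValidity("CentralityProfile", function(object) {
  msg <- character()
  if (!object@metricName %in% c("degree", "betweenness"))
    msg <- c(msg, "metricName must be 'degree' or 'betweenness'")
  if (nrow(object@values) != length(object@densities))
    msg <- c(msg, "one row of values per density required")
  if (ncol(object@values) != length(object@labels))
    msg <- c(msg, "one column of values per node required")
  if (length(object@densities) && any(diff(object@densities) <= 0))
    msg <- c(msg, "densities must be strictly increasing")
  if (any(object@values < 0))
    msg <- c(msg, "centrality values must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Density-integrated centrality (AUC across the sweep)
#'
#' One centrality value per node, obtained by summing the metric across
#' all densities of the sweep (an area under the curve over network
#' densities), the threshold-independent quantity all group inference
#' operates on.
#'
#' @slot metricName `"degree"` or `"betweenness"`.
#' @slot values named numeric vector, one value per node.
#' @slot labels character vector of parcel names.
#'
#' @seealso [integrateAcrossDensities()], [subjectCentrality()]
#' @export
setClass("IntegratedCentrality",
  slots = c(metricName = "character", values = "numeric", labels = "character")
)

setValidity("IntegratedCentrality", function(object) {
  msg <- character()
  if (length(object@values) != length(object@labels))
    msg <- c(msg, "one value per node required")
  if (length(msg)) msg else TRUE
})

#' Synthetic connectome cohort
#'
#' A simulated cohort: one [Connectome-class] per subject, a clinical
#' covariate table, the generating specification, and a truth record of
#' the planted parameters (effect node, realized latent effect size,
#' realized duration coupling) for validation of downstream inference.
#'
#' @slot connectomes list of [Connectome-class] objects.
#' @slot clinical data.frame with one row per subject (see
#'   [generateCohort()] for the column dictionary).
#' @slot truth list of planted/realized generative parameters.
#' @slot spec the [cohortSpec()] list the cohort was generated from.
#'
#' @seealso [generateCohort()], [writeCohort()], [readCohort()]
#' @export
setClass("SyntheticCohort",
  slots = c(
    connectomes = "list",
    clinical = "data.frame",
    truth = "list",
    spec = "list"
  )
)

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  ids <- vapply(object@connectomes, function(x) x@subjectID, character(1))
  if (length(ids) != nrow(object@clinical))
    msg <- c(msg, "one clinical record per connectome required")
  else if (!identical(ids, object@clinical$subject_id))
    msg <- c(msg, "connectome and clinical subject ids must match one-to-one")
  if (length(msg)) msg else TRUE
})
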