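# Plain-text serialization of cohorts.
#
# On-disk layout (one directory per cohort):
#   matrices/<subject>.tsv    tab-separated counts, header row and first
#                             column hold the node labels
#   waytotals/<subject>.tsv   two columns: label <TAB> waytotal
#   clinical.csv              one row per subject, literal "NA" for missing
#   truth.json                planted/realized generative parameters
#                             (synthetic cohorts only)

#' Write a cohort to a directory of delimited text files
#'
#' @param cohort a [SyntheticCohort-class] object, or a list with
#'   elements `connectomes` and `clinical`.
#' @param dir output directory (created if necessary).
#' @return `dir`, invisibly.
#' @seealso [readCohort()]
#' @export
writeCohort <- function(cohort, dir) {
  if (is(cohort, "SyntheticCohort")) {
    conns <- cohort@connectomes; clinical <- cohort@clinical
    truth <- cohort@truth
  } else {
    conns <- cohort$connectomes; clinical <- cohort$clinical
    truth <- cohort$truth
  }
  dir.create(file.path(dir, "matrices"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "waytotals"), showWarnings = FALSE)
  for (cn in conns) {
    m <- cn@counts
    utils::write.table(
      data.frame(label = rownames(m), m, check.names = FALSE),
      file.path(dir, "matrices", paste0(cn@subjectID, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(label = cn@labels, waytotal = cn@waytotals),
      file.path(dir, "waytotals", paste0(cn@subjectID, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.csv(clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE, na = "NA")
  if (!is.null(truth)) {
    writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                                null = "null"),
               file.path(dir, "truth.json"))
  }
  invisible(dir)
}

#' Read one connectome from delimited text
#'
#' Accepts any square labelled TSV/CSV matrix (the first column and the
#' header must carry identical node labels) plus a two-column
#' label/waytotal file. Validation failures (non-square matrix,
#' negative entry, nonzero diagonal, label mismatch) raise errors naming
#' the subject and, where applicable, the offending cell.
#'
#' @param matrixPath path to the count matrix file.
#' @param waytotalPath path to the waytotal file.
#' @param subjectID subject identifier (default: matrix file stem).
#' @param sep field separator (default tab).
#' @return A [Connectome-class] object.
#' @export
readConnectome <- function(matrixPath, waytotalPath,
                           subjectID = NULL, sep = "\t") {
  subjectID <- subjectID %||%
    sub("\\.[^.]+$", "", basename(matrixPath))
  tab <- utils::read.table(matrixPath, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m))
    stop("subject ", subjectID, ": matrix is not square (",
         nrow(m), " x ", ncol(m), ")")
  if (!identical(labels, colnames(m)))
    stop("subject ", subjectID, ": row labels do not match column labels")
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("subject ", subjectID, ": negative count at [",
         labels[bad[1, 1]], ", ", labels[bad[1, 2]], "]")
  if (any(diag(m) != 0))
    stop("subject ", subjectID, ": nonzero diagonal at ",
         labels[which(diag(m) != 0)[1L]])
  wt <- utils::read.table(waytotalPath, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!identical(as.character(wt[[1L]]), labels))
    stop("subject ", subjectID, ": waytotal labels do not match matrix labels")
  Connectome(m, wt[[2L]], labels = labels, subjectID = subjectID)
}

#' Read a cohort written by [writeCohort()]
#'
#' Reads every matrix under `matrices/`, the matching waytotal files and
#' the clinical table, and validates referential integrity: unique
#' subject ids, identical node-label sets across subjects, and a
#' one-to-one match between matrices and clinical rows.
#'
#' @param dir cohort directory.
#' @return List with elements `connectomes` (list of
#'   [Connectome-class]) and `clinical` (data.frame), plus `truth` when
#'   a `truth.json` is present.
#' @export
readCohort <- function(dir) {
  mfiles <- sort(list.files(file.path(dir, "matrices"), pattern = "\\.tsv$",
                            full.names = TRUE))
  if (!length(mfiles)) stop("no matrix files under ", dir, "/matrices")
  ids <- sub("\\.tsv$", "", basename(mfiles))
  if (anyDuplicated(ids))
    stop("duplicate subject ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  conns <- lapply(seq_along(mfiles), function(k) {
    readConnectome(mfiles[k],
                   file.path(dir, "waytotals", paste0(ids[k], ".tsv")),
                   subjectID = ids[k])
  })
  ref <- conns[[1L]]@labels
  for (cn in conns[-1L]) {
    if (!identical(cn@labels, ref))
      stop("subject ", cn@subjectID,
           ": node labels differ from those of ", conns[[1L]]@subjectID)
  }
  clinical <- utils::read.csv(file.path(dir, "clinical.csv"),
                              stringsAsFactors = FALSE,
                              colClasses = c(subject_id = "character"))
  unknown <- setdiff(clinical$subject_id, ids)
  if (length(unknown))
    stop("clinical table references unknown subject id(s): ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(ids, clinical$subject_id)
  if (length(missing))
    stop("no clinical record for subject(s): ",
         paste(missing, collapse = ", "))
  clinical <- clinical[match(ids, clinical$subject_id), , drop = FALSE]
  rownames(clinical) <- NULL
  out <- list(connectomes = conns, clinical = clinical)
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) out$truth <- jsonlite::fromJSON(tj)
  out
}
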