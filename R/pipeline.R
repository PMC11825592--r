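#' Analysis configuration
#'
#' Consolidates the constants of the study analysis: the density sweep,
#' the metrics, the primary regions of interest, the permutation budget
#' and the family-wise alpha. A single global `seed` is expanded into
#' per-test seeds through a fixed counter scheme (primary tests use
#' offsets 1000+k, exploratory degree tests 10000+node, exploratory
#' betweenness tests 20000+node, duration copulas nothing — they are
#' analytic — and surgery tests 30000+k), so permutation draws are
#' reproducible and uncorrelated across tests.
#'
#' @param densityLow,densityHigh,densityStep density sweep in integer
#'   percent (default 20/40/1).
#' @param metrics subset of `c("degree", "betweenness")`.
#' @param primaryNodes labels of the primary regions of interest
#'   (default: bilateral piriform cortex).
#' @param nPermutations permutations per primary/surgery test (default
#'   100,000).
#' @param exploratoryPermutations permutations per exploratory
#'   whole-network test (default: same as `nPermutations`; reduce for
#'   large scans).
#' @param familyAlpha family-wise alpha before correction (default
#'   0.05; the primary family of 4 tests is evaluated at 0.05/4 =
#'   0.0125, the surgical family at 0.05/10 = 0.005).
#' @param adjustNode node whose integrated degree is the response of
#'   the covariate-adjustment regressions (default: first primary
#'   node).
#' @param seed global analysis seed.
#' @return Validated list of class `"AnalysisConfig"`.
#' @export
analysisConfig <- function(densityLow = 20L, densityHigh = 40L,
                           densityStep = 1L,
                           metrics = c("degree", "betweenness"),
                           primaryNodes = c("lh_piriform", "rh_piriform"),
                           nPermutations = 100000L,
                           exploratoryPermutations = NULL,
                           familyAlpha = 0.05, adjustNode = NULL,
                           seed = 1L) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  sweepPercents(densityLow, densityHigh, densityStep)  # validates
  stopifnot(familyAlpha > 0, familyAlpha < 1, nPermutations >= 1)
  cfg <- list(
    densityLow = as.integer(densityLow),
    densityHigh = as.integer(densityHigh),
    densityStep = as.integer(densityStep),
    metrics = metrics,
    primaryNodes = primaryNodes,
    nPermutations = as.integer(nPermutations),
    exploratoryPermutations =
      as.integer(exploratoryPermutations %||% nPermutations),
    familyAlpha = familyAlpha,
    adjustNode = adjustNode %||% primaryNodes[[1L]],
    seed = as.integer(seed)
  )
  class(cfg) <- "AnalysisConfig"
  cfg
}

#' Read an analysis configuration from JSON or YAML
#'
#' Fields map one-to-one onto the arguments of [analysisConfig()];
#' unknown keys are rejected.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return An `"AnalysisConfig"` list.
#' @export
readAnalysisConfig <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  known <- names(formals(analysisConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(analysisConfig, vals)
}

# Accept a SyntheticCohort or a readCohort()-style list.
asCohortParts <- function(cohort) {
  if (is(cohort, "SyntheticCohort"))
    list(connectomes = cohort@connectomes, clinical = cohort@clinical)
  else if (is.list(cohort) && !is.null(cohort$connectomes))
    cohort
  else stop("cohort must be a SyntheticCohort or a readCohort() list")
}

#' Integrated centrality for every subject of a cohort
#'
#' Runs [subjectCentrality()]'s processing chain over all subjects and
#' assembles (subjects x nodes) matrices of density-integrated metric
#' values, plus a (subjects x densities) table of fragmentation flags.
#'
#' @param cohort a [SyntheticCohort-class] or [readCohort()] list.
#' @param config an [analysisConfig()] object.
#' @return List with per-metric matrices (`degree`, `betweenness`),
#'   `fragmented`, `labels` and `subjectIDs`.
#' @export
cohortCentrality <- function(cohort, config = analysisConfig()) {
  parts <- asCohortParts(cohort)
  conns <- parts$connectomes
  labels <- conns[[1L]]@labels
  ids <- vapply(conns, function(x) x@subjectID, character(1))
  pct <- sweepPercents(config$densityLow, config$densityHigh,
                       config$densityStep)
  out <- list(labels = labels, subjectIDs = ids)
  mats <- lapply(config$metrics, function(m)
    matrix(0, length(conns), length(labels), dimnames = list(ids, labels)))
  names(mats) <- config$metrics
  frag <- matrix(FALSE, length(conns), length(pct),
                 dimnames = list(ids, paste0(pct, "%")))
  for (s in seq_along(conns)) {
    # inline normalize + symmetrize (identical to processConnectome, minus
    # the per-subject S4 construction cost; equality is covered by tests)
    w <- conns[[s]]@counts / conns[[s]]@waytotals
    w <- (w + t(w)) / 2
    sw <- sweepCentrality(w, config$densityLow, config$densityHigh,
                          config$densityStep, metrics = config$metrics)
    for (m in config$metrics) mats[[m]][s, ] <- colSums(sw[[m]])
    frag[s, ] <- sw$fragmented
  }
  c(out, mats, list(fragmented = frag))
}

# Subjects usable for drug-resistance inference, with exclusion counts.
classifiedSubjects <- function(clinical) {
  keep <- !is.na(clinical$drug_resistant)
  list(keep = keep, nExcluded = sum(!keep))
}

#' Primary region-of-interest analysis
#'
#' The confirmatory arm of the study: two-sample permutation t-tests of
#' integrated centrality (each primary node x metric) between
#' drug-resistant and drug-sensitive subjects at the
#' Bonferroni-corrected alpha; Spearman correlations of the same
#' metrics with epilepsy duration (and, as a control, with age at MRI);
#' and OLS covariate adjustment of the adjust-node degree (model A:
#' resistance + duration; model B: additionally sex, laterality,
#' MRI-lesion dummy and onset age). Subjects with indeterminate drug
#' response are excluded and counted; missing durations are dropped
#' listwise and counted.
#'
#' @param cohort a [SyntheticCohort-class] or [readCohort()] list.
#' @param config an [analysisConfig()] object.
#' @param centrality optional precomputed [cohortCentrality()] result.
#' @return List with components `tests` (data.frame: node, metric, t,
#'   d, p, alpha, significant, nPermutations, exhaustive, seed),
#'   `correlations` (duration and age-at-MRI Spearman results),
#'   `adjusted` (the two `olsFit` objects, when degree is among the
#'   metrics), and `diagnostics`.
#' @export
runPrimary <- function(cohort, config = analysisConfig(),
                       centrality = NULL) {
  parts <- asCohortParts(cohort)
  clinical <- parts$clinical
  cc <- centrality %||% cohortCentrality(cohort, config)
  missingNodes <- setdiff(config$primaryNodes, cc$labels)
  if (length(missingNodes))
    stop("primary node(s) not in the network: ",
         paste(missingNodes, collapse = ", "))
  cls <- classifiedSubjects(clinical)
  grp <- clinical$drug_resistant
  if (sum(grp %in% TRUE) < 2L || sum(grp %in% FALSE) < 2L)
    stop("need at least 2 subjects per drug-response group")

  nTests <- length(config$primaryNodes) * length(config$metrics)
  alpha <- bonferroniAlpha(config$familyAlpha, nTests)
  rows <- list(); k <- 0L
  for (node in config$primaryNodes) {
    for (m in config$metrics) {
      k <- k + 1L
      v <- cc[[m]][, node]
      res <- permutationTwoSample(v[grp %in% TRUE], v[grp %in% FALSE],
                                  nPermutations = config$nPermutations,
                                  seed = deriveSeed(config$seed, 1000L + k))
      rows[[k]] <- data.frame(
        node = node, metric = m, t = res$t, d = res$d, p = res$p,
        alpha = alpha, significant = res$p < alpha,
        nPermutations = res$nPermutations, exhaustive = res$exhaustive,
        seed = res$seed, stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, rows)

  corRows <- list(); k <- 0L
  durOK <- cls$keep & !is.na(clinical$duration_years)
  ageOK <- cls$keep & !is.na(clinical$age_at_mri)
  # too few (or degenerate) pairs yield NA rather than aborting the report
  safeSpearman <- function(x, y) {
    if (length(x) < 4L) return(list(rho = NA_real_, p = NA_real_,
                                    n = length(x)))
    tryCatch(spearmanCorr(x, y),
             error = function(e) list(rho = NA_real_, p = NA_real_,
                                      n = length(x)))
  }
  for (node in config$primaryNodes) {
    for (m in config$metrics) {
      k <- k + 1L
      dres <- safeSpearman(cc[[m]][durOK, node],
                           clinical$duration_years[durOK])
      ares <- safeSpearman(cc[[m]][ageOK, node],
                           clinical$age_at_mri[ageOK])
      corRows[[k]] <- data.frame(
        node = node, metric = m,
        rho = dres$rho, p = dres$p, n = dres$n, alpha = alpha,
        significant = dres$p < alpha,
        rhoAgeControl = ares$rho, pAgeControl = ares$p,
        stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, corRows)

  adjusted <- NULL
  if ("degree" %in% config$metrics && config$adjustNode %in% cc$labels) {
    y <- cc$degree[cls$keep, config$adjustNode]
    cl <- clinical[cls$keep, , drop = FALSE]
    base <- data.frame(
      drug_resistant = cl$drug_resistant,
      duration_years = cl$duration_years)
    full <- cbind(base, data.frame(
      sex = factor(cl$sex),
      laterality = stats::relevel(factor(cl$laterality,
        levels = c("left", "right", "bilateral", "unclear")[
          c("left", "right", "bilateral", "unclear") %in% cl$laterality]),
        ref = "left"),
      lesion_mri = cl$lesion_mri,
      onset_age = cl$onset_age))
    # cohorts too small (or too collinear) for a model are reported as such
    tryOls <- function(design) {
      tryCatch(olsAdjust(y, design),
               error = function(e) list(notEvaluable = conditionMessage(e)))
    }
    adjusted <- list(
      durationOnly = tryOls(base),
      fullCovariates = tryOls(full))
  }

  diagnostics <- list(
    nSubjects = nrow(clinical),
    nClassified = sum(cls$keep),
    nExcludedUnclassified = cls$nExcluded,
    nMissingDuration = sum(cls$keep & is.na(clinical$duration_years)),
    fragmentedSubjectDensities = sum(cc$fragmented),
    smallSampleExhaustive = any(tests$exhaustive),
    seed = config$seed,
    packageVersion = as.character(utils::packageVersion("netcentral"))
  )
  list(tests = tests, correlations = correlations, adjusted = adjusted,
       diagnostics = diagnostics)
}

#' Exploratory whole-network scan
#'
#' For every node and metric: the group t statistic, Cohen's d, a raw
#' permutation p-value and its Benjamini-Hochberg adjustment over all
#' nodes (m = node count); plus, per node, the Spearman correlation of
#' the metric with epilepsy duration, BH-adjusted the same way. Tables
#' are sorted by descending effect size.
#'
#' @inheritParams runPrimary
#' @return List with one data.frame per metric (`degree`,
#'   `betweenness`) and per duration correlation table
#'   (`durationDegree`, `durationBetweenness`).
#' @export
runExploratory <- function(cohort, config = analysisConfig(),
                           centrality = NULL) {
  parts <- asCohortParts(cohort)
  clinical <- parts$clinical
  cc <- centrality %||% cohortCentrality(cohort, config)
  grp <- clinical$drug_resistant
  durOK <- !is.na(grp) & !is.na(clinical$duration_years)
  out <- list()
  offsets <- c(degree = 10000L, betweenness = 20000L)
  for (m in config$metrics) {
    vals <- cc[[m]]
    n <- ncol(vals)
    t <- d <- p <- numeric(n)
    for (j in seq_len(n)) {
      res <- permutationTwoSample(
        vals[grp %in% TRUE, j], vals[grp %in% FALSE, j],
        nPermutations = config$exploratoryPermutations,
        seed = deriveSeed(config$seed, offsets[[m]] + j))
      t[j] <- res$t; d[j] <- res$d; p[j] <- res$p
    }
    tab <- data.frame(node = cc$labels, t = t, d = d, p = p,
                      pFDR = fdrBH(p), m = n, stringsAsFactors = FALSE)
    out[[m]] <- tab[order(-tab$d), , drop = FALSE]

    rho <- pc <- numeric(n)
    for (j in seq_len(n)) {
      res <- spearmanCorr(vals[durOK, j], clinical$duration_years[durOK])
      rho[j] <- res$rho; pc[j] <- res$p
    }
    dtab <- data.frame(node = cc$labels, rho = rho, p = pc,
                       pFDR = fdrBH(pc), m = n, stringsAsFactors = FALSE)
    nm <- paste0("duration", toupper(substring(m, 1, 1)), substring(m, 2))
    out[[nm]] <- dtab[order(-dtab$rho), , drop = FALSE]
  }
  out
}

#' Surgical-outcome subanalysis
#'
#' Among operated subjects with at least one year of postoperative
#' follow-up, compares integrated centrality of each candidate node
#' between completely seizure-free (ILAE class 1) and not seizure-free
#' subjects by permutation t-test at `familyAlpha / 10`. A negative
#' Cohen's d means smaller centrality in the seizure-free group.
#'
#' @inheritParams runPrimary
#' @param candidateNodes node labels to test (default: the primary
#'   nodes).
#' @return List with `evaluable` flag, the test table and the subject
#'   counts; when either outcome group has fewer than 2 subjects, the
#'   report is marked not evaluable and no tests are run.
#' @export
runSurgery <- function(cohort, config = analysisConfig(),
                       candidateNodes = config$primaryNodes,
                       centrality = NULL) {
  parts <- asCohortParts(cohort)
  clinical <- parts$clinical
  cc <- centrality %||% cohortCentrality(cohort, config)
  elig <- clinical$operated %in% TRUE &
    !is.na(clinical$followup_years) & clinical$followup_years >= 1 &
    !is.na(clinical$ilae_class)
  seizureFree <- elig & clinical$ilae_class == 1L
  notFree <- elig & clinical$ilae_class != 1L
  counts <- list(nOperatedEligible = sum(elig),
                 nSeizureFree = sum(seizureFree),
                 nNotSeizureFree = sum(notFree))
  if (sum(seizureFree) < 2L || sum(notFree) < 2L) {
    return(c(list(evaluable = FALSE, tests = NULL,
                  reason = "fewer than 2 subjects in an outcome group"),
             counts))
  }
  alpha <- bonferroniAlpha(config$familyAlpha, 10L)
  rows <- list(); k <- 0L
  for (node in candidateNodes) {
    for (m in config$metrics) {
      k <- k + 1L
      v <- cc[[m]][, node]
      res <- permutationTwoSample(v[seizureFree], v[notFree],
                                  nPermutations = config$nPermutations,
                                  seed = deriveSeed(config$seed, 30000L + k))
      rows[[k]] <- data.frame(
        node = node, metric = m, t = res$t, d = res$d, p = res$p,
        alpha = alpha, significant = res$p < alpha,
        direction = ifelse(res$d < 0, "smaller in seizure-free",
                           "larger in seizure-free"),
        nPermutations = res$nPermutations, exhaustive = res$exhaustive,
        seed = res$seed, stringsAsFactors = FALSE)
    }
  }
  c(list(evaluable = TRUE, tests = do.call(rbind, rows)), counts)
}

#' Run the complete study analysis
#'
#' Computes centrality once and runs the primary, exploratory and
#' surgical analyses. With `outDir` set, writes `report.json`,
#' `primary.csv`, `correlations.csv`, `exploratory_degree.csv`,
#' `exploratory_bc.csv` and `surgery.csv`. The report is deterministic:
#' the same config and input produce byte-identical output (no
#' timestamps).
#'
#' @inheritParams runPrimary
#' @param outDir optional output directory.
#' @return List of class `"AnalysisReport"` with sections `primary`,
#'   `exploratory`, `surgery`, `config`.
#' @export
runStudy <- function(cohort, config = analysisConfig(), outDir = NULL) {
  cc <- cohortCentrality(cohort, config)
  report <- list(
    primary = runPrimary(cohort, config, centrality = cc),
    exploratory = runExploratory(cohort, config, centrality = cc),
    surgery = runSurgery(cohort, config, centrality = cc),
    config = unclass(config)
  )
  class(report) <- "AnalysisReport"
  if (!is.null(outDir)) writeReport(report, outDir)
  report
}

#' Write an analysis report to disk
#'
#' @param report an `"AnalysisReport"` from [runStudy()].
#' @param outDir output directory (created if necessary).
#' @return `outDir`, invisibly.
#' @export
writeReport <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) if (!is.null(x))
    utils::write.csv(x, file.path(outDir, f), row.names = FALSE, na = "NA")
  wcsv(report$primary$tests, "primary.csv")
  wcsv(report$primary$correlations, "correlations.csv")
  wcsv(report$exploratory$degree, "exploratory_degree.csv")
  wcsv(report$exploratory$betweenness, "exploratory_bc.csv")
  wcsv(report$surgery$tests, "surgery.csv")
  slim <- rapply(unclass(report), function(x) x, how = "replace")
  stripFit <- function(x) {
    if (is.list(x)) {
      x$fit <- NULL
      lapply(x, stripFit)
    } else x
  }
  slim <- stripFit(slim)
  writeLines(jsonlite::toJSON(slim, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null", force = TRUE),
             file.path(outDir, "report.json"))
  invisible(outDir)
}

#' @export
print.AnalysisReport <- function(x, ...) {
  cat("Study analysis report\n")
  cat("  primary tests (alpha =", x$primary$tests$alpha[1], "):\n")
  print(x$primary$tests[, c("node", "metric", "t", "d", "p",
                            "significant")], row.names = FALSE)
  cat("  duration correlations:\n")
  print(x$primary$correlations[, c("node", "metric", "rho", "p",
                                   "significant")], row.names = FALSE)
  if (isTRUE(x$surgery$evaluable)) {
    cat("  surgery subanalysis (alpha =", x$surgery$tests$alpha[1], "):\n")
    print(x$surgery$tests[, c("node", "metric", "t", "d", "p",
                              "direction")], row.names = FALSE)
  } else {
    cat("  surgery subanalysis: not evaluable\n")
  }
  invisible(x)
}
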