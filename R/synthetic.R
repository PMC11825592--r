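#' Specification of a synthetic connectome cohort
#'
#' Collects all generative parameters of a simulated cohort. The
#' defaults emulate the study conditions the pipeline is designed for:
#' 82 network nodes, 43 drug-resistant and 19 drug-sensitive subjects
#' plus 2 subjects with indeterminate drug response (excluded from group
#' tests), a planted standardized group difference of 0.85 on the left
#' piriform node's integrated degree, and a duration covariate
#' rank-coupled to that node's centrality at Spearman rho 0.39.
#'
#' @param nNodes number of network nodes (>= 3).
#' @param nGroupA number of drug-resistant subjects.
#' @param nGroupB number of drug-sensitive subjects.
#' @param nUnclassified subjects with indeterminate drug response
#'   (carried in the cohort, excluded from group inference).
#' @param effectNode label of the node receiving the planted effect.
#' @param degreeEffectD target standardized group difference (Cohen's
#'   d) of the effect node's integrated degree.
#' @param durationRho target Spearman correlation between epilepsy
#'   duration and the effect node's centrality, in [-1, 1].
#' @param baseDensity expected fraction of nonzero connections in the
#'   raw matrices; must exceed 0.4 so every subject remains connected at
#'   the 20% proportional threshold.
#' @param weightScale mean streamline count per connected pair.
#' @param noiseCV coefficient of variation of the subject-level
#'   multiplicative edge-weight noise.
#' @param betaScale slope mapping the latent severity trait to the
#'   log of the per-subject effect-node scaling factor.
#' @param effectKappa calibration constant inflating the latent trait
#'   shift so the *realized* Cohen's d of integrated degree (after
#'   thresholding noise) matches `degreeEffectD` on average.
#' @param operatedFraction probability that a classified subject has
#'   received epilepsy surgery (unclassified subjects are always
#'   operated, mirroring subjects with only surgical follow-up data).
#' @param outcomeIntercept,outcomeSlope logistic model of a completely
#'   seizure-free (ILAE class 1) surgical outcome: `P(ILAE 1) =
#'   plogis(outcomeIntercept - outcomeSlope * trait)`, so higher
#'   effect-node centrality means lower odds of seizure freedom.
#' @param nMissingDuration number of classified subjects whose duration
#'   is set missing (exercises listwise deletion downstream).
#' @param seed integer RNG seed; the cohort is fully reproducible from
#'   the spec.
#' @param labels optional node labels; defaults to
#'   [defaultNodeLabels()] for 82 nodes and generated labels (always
#'   including both piriform ROIs) otherwise.
#' @return A validated list of class `"CohortSpec"`.
#' @seealso [generateCohort()]
#' @export
cohortSpec <- function(nNodes = 82L, nGroupA = 43L, nGroupB = 19L,
                       nUnclassified = 2L, effectNode = "lh_piriform",
                       degreeEffectD = 0.85, durationRho = 0.39,
                       baseDensity = 0.6, weightScale = 200,
                       noiseCV = 0.3, betaScale = 0.35, effectKappa = 1.12,
                       operatedFraction = 0.42, outcomeIntercept = 0,
                       outcomeSlope = 1.5, nMissingDuration = 1L,
                       seed = 1L, labels = NULL) {
  if (nNodes < 3L) stop("nNodes must be at least 3")
  spec <- list(
    nNodes = as.integer(nNodes), nGroupA = as.integer(nGroupA),
    nGroupB = as.integer(nGroupB), nUnclassified = as.integer(nUnclassified),
    effectNode = effectNode, degreeEffectD = degreeEffectD,
    durationRho = durationRho, baseDensity = baseDensity,
    weightScale = weightScale, noiseCV = noiseCV, betaScale = betaScale,
    effectKappa = effectKappa, operatedFraction = operatedFraction,
    outcomeIntercept = outcomeIntercept, outcomeSlope = outcomeSlope,
    nMissingDuration = as.integer(nMissingDuration), seed = as.integer(seed),
    labels = labels %||% syntheticNodeLabels(as.integer(nNodes))
  )
  validateCohortSpec(spec)
  class(spec) <- "CohortSpec"
  spec
}

validateCohortSpec <- function(spec) {
  if (spec$nNodes < 3L)
    stop("nNodes must be at least 3")
  if (spec$nGroupA + spec$nGroupB < 4L)
    stop("need at least 4 classified subjects (nGroupA + nGroupB >= 4)")
  if (spec$nGroupA < 2L || spec$nGroupB < 2L)
    stop("each group needs at least 2 subjects")
  if (spec$nUnclassified < 0L)
    stop("nUnclassified must be nonnegative")
  if (spec$baseDensity <= 0.4 || spec$baseDensity > 1)
    stop("baseDensity must lie in (0.4, 1] so networks stay connected ",
         "at the 20% proportional threshold")
  if (abs(spec$durationRho) > 1)
    stop("durationRho must lie in [-1, 1]")
  if (spec$durationRho != 0 && spec$betaScale == 0)
    stop("infeasible spec: duration coupling requested but the planted ",
         "effect has zero variance (betaScale = 0)")
  if (spec$noiseCV < 0 || spec$weightScale <= 0)
    stop("noiseCV must be nonnegative and weightScale positive")
  if (length(spec$labels) != spec$nNodes || anyDuplicated(spec$labels))
    stop("labels must be unique and match nNodes")
  if (!spec$effectNode %in% spec$labels)
    stop("effectNode '", spec$effectNode, "' not among the node labels")
  invisible(TRUE)
}

# Latent symmetric "anatomy": a connected random graph on n nodes with
# heavy-tailed (log-normal) edge weights around weightScale. Regenerated
# up to maxRetry times if the drawn edge set is disconnected.
anatomyTemplate <- function(n, baseDensity, weightScale, maxRetry = 25L) {
  npairs <- n * (n - 1L) / 2L
  for (attempt in seq_len(maxRetry)) {
    present <- stats::runif(npairs) < baseDensity
    ij <- which(upper.tri(matrix(0, n, n)))
    w <- matrix(0, n, n)
    wt <- stats::rlnorm(sum(present), meanlog = log(weightScale) - 0.5,
                        sdlog = 1)
    w[ij[present]] <- wt
    w <- w + t(w)
    g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
    if (igraph::components(g)$no == 1L) return(w)
  }
  stop("could not draw a connected anatomy template at baseDensity = ",
       baseDensity, " after ", maxRetry, " attempts")
}

# Independent multiplicative log-normal noise per direction (mean 1,
# coefficient of variation noiseCV), then rounding to integer counts.
perturbCounts <- function(template, noiseCV) {
  n <- nrow(template)
  if (noiseCV > 0) {
    sdl <- sqrt(log(1 + noiseCV^2))
    noise <- matrix(stats::rlnorm(n * n, meanlog = -sdl^2 / 2, sdlog = sdl),
                    n, n)
  } else {
    noise <- matrix(1, n, n)
  }
  counts <- round(template * noise)
  diag(counts) <- 0
  counts
}

# Waytotals model: 5000 streamlines seeded per voxel of each region times
# a per-region voxel-count proxy drawn once. Seeding-dependent, hence
# deliberately NOT equal to the row sums of the count matrix.
drawWaytotals <- function(n) {
  vox <- round(stats::rlnorm(n, meanlog = log(400), sdlog = 0.3))
  5000 * pmax(vox, 1)
}

#' Generate one synthetic raw connectome
#'
#' Draws a latent symmetric anatomy template (a connected random graph
#' with heavy-tailed streamline weights) and perturbs it with
#' independent multiplicative noise per direction, emulating the
#' asymmetric streamline-count matrices produced by probabilistic
#' tractography. Waytotals are drawn from a seeding model (streamlines
#' per voxel times a region-size proxy) and are intentionally distinct
#' from the matrix row sums.
#'
#' @param nNodes number of nodes (>= 3).
#' @param baseDensity expected fraction of nonzero connections, in
#'   (0, 1].
#' @param weightScale mean streamline count per connected pair.
#' @param seed integer RNG seed; the result is deterministic given the
#'   seed.
#' @param noiseCV coefficient of variation of the directional noise.
#' @param labels optional node labels.
#' @param subjectID subject identifier.
#' @return A [Connectome-class] object.
#' @examples
#' cn <- generateBaseConnectome(5, baseDensity = 1, weightScale = 100,
#'                              seed = 1)
#' streamlineCounts(cn)
#' @export
generateBaseConnectome <- function(nNodes, baseDensity = 0.6,
                                   weightScale = 200, seed = 1L,
                                   noiseCV = 0.3, labels = NULL,
                                   subjectID = "subject") {
  stopifnot(nNodes >= 3L, baseDensity > 0, baseDensity <= 1, weightScale > 0)
  labels <- labels %||% syntheticNodeLabels(as.integer(nNodes))
  withSeed(seed, {
    tmpl <- anatomyTemplate(nNodes, baseDensity, weightScale)
    counts <- perturbCounts(tmpl, noiseCV)
    Connectome(counts, drawWaytotals(nNodes), labels = labels,
               subjectID = subjectID)
  })
}

#' Plant a centrality effect on one node
#'
#' Multiplies all streamline counts in the given node's row and column
#' by `scale` (re-rounded to integer counts), leaving every other entry
#' untouched. This raises (for `scale > 1`) the node's normalized
#' connection strengths and hence its degree and betweenness after
#' thresholding. Waytotals are recomputed under the seeding model, which
#' does not depend on the counts, so they are unchanged.
#'
#' @param x a [Connectome-class] object.
#' @param node label of the node to scale.
#' @param scale positive multiplicative factor.
#' @return A new [Connectome-class] object.
#' @examples
#' cn <- generateBaseConnectome(5, baseDensity = 0.8, seed = 2)
#' boosted <- plantCentralityEffect(cn, "lh_piriform", 10)
#' @export
plantCentralityEffect <- function(x, node, scale) {
  stopifnot(is(x, "Connectome"))
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("scale must be a single positive number")
  idx <- match(node, x@labels)
  if (is.na(idx))
    stop("unknown node label '", node, "'")
  counts <- x@counts
  counts[idx, ] <- round(counts[idx, ] * scale)
  counts[, idx] <- round(counts[, idx] * scale)
  counts[idx, idx] <- 0
  Connectome(counts, x@waytotals, labels = x@labels, subjectID = x@subjectID)
}

#' Generate a full synthetic cohort
#'
#' Simulates a cohort of streamline-count connectomes plus a clinical
#' covariate table with the statistical structure the inference layer
#' assumes:
#' \itemize{
#'   \item all subjects share one latent anatomy template (drawn once
#'     per cohort); between-subject variation enters through directional
#'     multiplicative noise;
#'   \item each subject carries a latent severity trait (standard normal,
#'     shifted by `effectKappa * degreeEffectD` in the drug-resistant
#'     group); the effect node's incident counts are scaled by
#'     `exp(betaScale * trait)` via [plantCentralityEffect()];
#'   \item epilepsy duration (years, right-skewed gamma marginal) is
#'     rank-coupled to the trait through a Gaussian copula so the
#'     realized Spearman correlation with the planted effect
#'     approximates `durationRho`;
#'   \item sex, TLE laterality, MRI-lesion dummy, onset age and age at
#'     MRI are drawn independently with cohort-realistic marginals;
#'   \item a configurable subset is "operated"; a completely
#'     seizure-free ILAE class 1 outcome is assigned with probability
#'     decreasing in the severity trait.
#' }
#' The cohort, including the truth record of planted and realized
#' parameters, is fully deterministic given the spec (which includes the
#' seed).
#'
#' @param spec a [cohortSpec()] object.
#' @return A [SyntheticCohort-class] object. The clinical table has
#'   columns `subject_id`, `drug_resistant` (logical, `NA` =
#'   indeterminate), `duration_years`, `age_at_mri`, `sex`,
#'   `laterality`, `lesion_mri` (0 = lesional MRI or hippocampal
#'   sclerosis, 1 = other lesion), `onset_age`, `operated`,
#'   `ilae_class` (1--6, `NA` if not operated), `followup_years`.
#' @examples
#' co <- generateCohort(cohortSpec(nNodes = 12, nGroupA = 6, nGroupB = 4,
#'                                 nUnclassified = 0, seed = 7))
#' co
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  validateCohortSpec(spec)
  withSeed(spec$seed, {
    nTot <- spec$nGroupA + spec$nGroupB + spec$nUnclassified
    ids <- sprintf("sub%03d", seq_len(nTot))
    group <- c(rep(TRUE, spec$nGroupA), rep(FALSE, spec$nGroupB),
               rep(NA, spec$nUnclassified))

    # latent severity trait and per-subject effect scales
    delta <- spec$effectKappa * spec$degreeEffectD
    trait <- stats::rnorm(nTot) + ifelse(group %in% TRUE, delta, 0)
    scales <- exp(spec$betaScale * trait)

    # shared anatomy, subject-level noise, planted effect
    tmpl <- anatomyTemplate(spec$nNodes, spec$baseDensity, spec$weightScale)
    conns <- lapply(seq_len(nTot), function(i) {
      counts <- perturbCounts(tmpl, spec$noiseCV)
      cn <- Connectome(counts, drawWaytotals(spec$nNodes),
                       labels = spec$labels, subjectID = ids[i])
      plantCentralityEffect(cn, spec$effectNode, scales[i])
    })

    # duration via Gaussian copula on the normal scores of the trait ranks:
    # targets the Spearman correlation exactly, independent of marginals
    ns <- stats::qnorm((rank(trait) - 0.5) / nTot)
    rhoN <- 2 * sin(pi * spec$durationRho / 6)
    lat <- rhoN * ns + sqrt(max(0, 1 - rhoN^2)) * stats::rnorm(nTot)
    duration <- stats::qgamma(stats::pnorm(lat), shape = 2, scale = 8)

    # independent clinical marginals
    sex <- sample(c("female", "male"), nTot, replace = TRUE,
                  prob = c(0.581, 0.419))
    laterality <- sample(c("left", "right", "bilateral", "unclear"), nTot,
                         replace = TRUE, prob = c(0.597, 0.322, 0.065, 0.016))
    lesion <- stats::rbinom(nTot, 1L, 0.25)
    onset <- pmax(1, round(stats::rgamma(nTot, shape = 2.5, scale = 7), 1))
    ageAtMri <- round(pmin(pmax(stats::rnorm(nTot, 40, 12), 18), 75), 1)

    operated <- stats::rbinom(nTot, 1L, spec$operatedFraction) == 1L
    operated[is.na(group)] <- TRUE  # unclassified: surgery data only
    traitStd <- as.numeric(scale(trait))
    p1 <- stats::plogis(spec$outcomeIntercept - spec$outcomeSlope * traitStd)
    ilae <- rep(NA_integer_, nTot)
    fup <- rep(NA_real_, nTot)
    isOp <- which(operated)
    seizureFree <- stats::rbinom(length(isOp), 1L, p1[isOp]) == 1L
    ilae[isOp] <- ifelse(seizureFree, 1L,
                         sample(2:6, length(isOp), replace = TRUE))
    fup[isOp] <- round(stats::rgamma(length(isOp), shape = 2, scale = 2), 1)

    if (spec$nMissingDuration > 0L) {
      classified <- which(!is.na(group))
      drop <- sample(classified,
                     min(spec$nMissingDuration, length(classified)))
      duration[drop] <- NA_real_
    }

    clinical <- data.frame(
      subject_id = ids,
      drug_resistant = group,
      duration_years = round(duration, 1),
      age_at_mri = ageAtMri,
      sex = sex,
      laterality = laterality,
      lesion_mri = lesion,
      onset_age = onset,
      operated = operated,
      ilae_class = ilae,
      followup_years = fup,
      stringsAsFactors = FALSE
    )

    cc <- !is.na(clinical$duration_years)
    realizedRho <- if (sum(cc) >= 4L)
      spearmanCorr(scales[cc], clinical$duration_years[cc])$rho
    else NA_real_
    truth <- list(
      effectNode = spec$effectNode,
      traitShift = delta,
      betaScale = spec$betaScale,
      traits = trait,
      scales = scales,
      realizedTraitD = cohensD(trait[group %in% TRUE], trait[group %in% FALSE]),
      realizedScaleDurationRho = realizedRho,
      seed = spec$seed
    )

    sp <- spec
    class(sp) <- "list"
    new("SyntheticCohort", connectomes = conns, clinical = clinical,
        truth = truth, spec = sp)
  })
}
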