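# Inferential layer: permutation group tests, effect sizes, rank
# correlations, covariate-adjusted OLS, and multiplicity control.

# Pooled-variance two-sample t statistic from subset sums; the permutation
# loop recomputes this from cumulative quantities for speed.
pooledT <- function(meanA, meanB, pooledVar, nA, nB) {
  (meanA - meanB) / sqrt(pooledVar * (1 / nA + 1 / nB))
}

#' Two-sample permutation t-test
#'
#' Compares two groups with the pooled-variance two-sample t statistic;
#' the null distribution is built by randomly reassigning group labels
#' while preserving group sizes. The two-tailed Monte-Carlo p-value uses
#' add-one smoothing, `p = (1 + #{|t*| >= |t|}) / (B + 1)`, so it is
#' never exactly zero. When the number of distinct label assignments
#' `choose(nA + nB, nA)` does not exceed `nPermutations`, the test
#' switches to exhaustive enumeration and the p-value is exact.
#'
#' @param a,b numeric vectors of at least 2 finite values each.
#' @param nPermutations number of random label permutations (default
#'   100,000).
#' @param seed integer seed for the permutation draw (ignored in
#'   exhaustive mode).
#' @param exhaustive force (`TRUE`) or forbid (`FALSE`) exhaustive
#'   enumeration; default `NULL` auto-enables it when cheap.
#' @param welch use the Welch (unequal-variance) statistic instead of
#'   the pooled-variance t.
#' @return List of class `"groupTest"`: `t`, `p`, `d` (Cohen's d,
#'   pooled SD), `nA`, `nB`, `nPermutations` (actual null draws),
#'   `exhaustive`, `seed`.
#' @examples
#' r <- permutationTwoSample(c(1, 2, 3), c(4, 5, 6))
#' r$p  # exact: 2/20 over all choose(6,3) assignments
#' @export
permutationTwoSample <- function(a, b, nPermutations = 100000L, seed = 1L,
                                 exhaustive = NULL, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("groups must contain finite values only")
  nA <- length(a); nB <- length(b); n <- nA + nB
  x <- c(a, b)
  sx <- sum(x); sxx <- sum(x^2)

  tFromSubset <- if (welch) {
    function(sA, sAq) {
      mA <- sA / nA; mB <- (sx - sA) / nB
      vA <- (sAq - nA * mA^2) / (nA - 1)
      vB <- ((sxx - sAq) - nB * mB^2) / (nB - 1)
      (mA - mB) / sqrt(vA / nA + vB / nB)
    }
  } else {
    function(sA, sAq) {
      mA <- sA / nA; mB <- (sx - sA) / nB
      pv <- (sxx - nA * mA^2 - nB * mB^2) / (n - 2)
      (mA - mB) / sqrt(pv * (1 / nA + 1 / nB))
    }
  }

  sA0 <- sum(a); sAq0 <- sum(a^2)
  pv0 <- (sxx - nA * (sA0 / nA)^2 - nB * ((sx - sA0) / nB)^2) / (n - 2)
  if (pv0 <= .Machine$double.eps * max(1, sxx / n)) {
    # degenerate: no pooled variance at all
    if (isTRUE(all.equal(sort(a), sort(b))) || stats::var(x) == 0) {
      return(structure(list(t = 0, p = 1, d = 0, nA = nA, nB = nB,
                            nPermutations = 0L, exhaustive = TRUE,
                            seed = seed), class = "groupTest"))
    }
    stop("t statistic undefined: zero pooled variance with unequal groups")
  }
  tObs <- tFromSubset(sA0, sAq0)

  nAssign <- choose(n, nA)
  doExhaustive <- exhaustive %||% (nAssign <= nPermutations)
  eps <- 1e-12 * max(1, abs(tObs))
  if (doExhaustive) {
    idx <- utils::combn(n, nA)
    tPerm <- apply(idx, 2L, function(ii) tFromSubset(sum(x[ii]),
                                                     sum(x[ii]^2)))
    p <- sum(abs(tPerm) >= abs(tObs) - eps) / ncol(idx)
    B <- ncol(idx)
  } else {
    B <- as.integer(nPermutations)
    exceed <- withSeed(seed, {
      cnt <- 0L
      for (r in seq_len(B)) {
        ii <- sample.int(n, nA)
        tp <- tFromSubset(sum(x[ii]), sum(x[ii]^2))
        if (abs(tp) >= abs(tObs) - eps) cnt <- cnt + 1L
      }
      cnt
    })
    p <- (1 + exceed) / (B + 1)
  }
  structure(list(t = tObs, p = p, d = cohensD(a, b), nA = nA, nB = nB,
                 nPermutations = B, exhaustive = doExhaustive, seed = seed),
            class = "groupTest")
}

#' Cohen's d with pooled standard deviation
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled` with
#' `s_pooled^2 = ((nA-1) sA^2 + (nB-1) sB^2) / (nA + nB - 2)` using
#' sample variances. No small-sample (Hedges) correction is applied;
#' with this definition `t = d * sqrt(nA nB / (nA + nB))` for the
#' pooled-variance t statistic.
#'
#' @param a,b numeric vectors of at least 2 values each.
#' @return Cohen's d (unitless).
#' @examples
#' cohensD(c(0, 2), c(1, 3))  # -1/sqrt(2)
#' @export
cohensD <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  nA <- length(a); nB <- length(b)
  sp2 <- ((nA - 1) * stats::var(a) + (nB - 1) * stats::var(b)) / (nA + nB - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (ties allowed), with the two-tailed
#' p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y paired numeric vectors, `n >= 4`, no missing values
#'   (drop incomplete pairs beforehand).
#' @return List of class `"rankCorrelation"`: `rho`, `p`, `n`.
#' @examples
#' spearmanCorr(1:10, (1:10)^3)$rho  # 1: invariant to monotone transforms
#' @export
spearmanCorr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (anyNA(x) || anyNA(y)) stop("missing values: drop incomplete pairs first")
  n <- length(x)
  if (n < 4L) stop("need at least 4 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: rank correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tv <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tv), df = n - 2)
  }
  structure(list(rho = rho, p = p, n = n), class = "rankCorrelation")
}

#' Covariate adjustment by ordinary least squares
#'
#' Fits `y ~ .` on the supplied regressors with an intercept, using
#' listwise deletion of records with any missing value (the number
#' dropped is reported). Factors are expanded by treatment coding.
#'
#' @param y numeric response.
#' @param design data.frame of named regressors (numeric, logical or
#'   factor), same length as `y`.
#' @return List of class `"olsFit"`: `terms`, `coefficients`, `se`,
#'   `t`, `p` (per-term, two-tailed from the t distribution),
#'   `adjRSquared`, `fStatistic`, `fP`, `dfModel`, `dfResidual`,
#'   `nUsed`, `nDropped`, and the underlying `lm` fit.
#' @examples
#' d <- data.frame(xx = rnorm(20))
#' olsAdjust(2 * d$xx + rnorm(20), d)$coefficients
#' @export
olsAdjust <- function(y, design) {
  stopifnot(is.data.frame(design), nrow(design) == length(y))
  dat <- cbind(data.frame(.y = y), design)
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  fit <- stats::lm(.y ~ ., data = dat)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  sm <- summary(fit)
  if (nrow(dat) <= length(stats::coef(fit)))
    stop("too few complete records for the number of terms")
  fs <- sm$fstatistic
  structure(list(
    terms = rownames(sm$coefficients),
    coefficients = sm$coefficients[, "Estimate"],
    se = sm$coefficients[, "Std. Error"],
    t = sm$coefficients[, "t value"],
    p = sm$coefficients[, "Pr(>|t|)"],
    adjRSquared = sm$adj.r.squared,
    fStatistic = unname(fs["value"]),
    fP = stats::pf(fs["value"], fs["numdf"], fs["dendf"],
                   lower.tail = FALSE),
    dfModel = unname(fs["numdf"]),
    dfResidual = unname(fs["dendf"]),
    nUsed = nrow(dat),
    nDropped = sum(!cc),
    fit = fit
  ), class = "olsFit")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: sort ascending, multiply
#' `p_(i)` by `m / i`, enforce monotonicity from the largest rank down,
#' cap at 1, and return in the original order (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' fdrBH(c(0.01, 0.04, 0.03))  # 0.03 0.04 0.04
#' @export
fdrBH <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Bonferroni-corrected alpha level
#'
#' @param alpha family-wise alpha in (0, 1).
#' @param m number of comparisons in the family.
#' @return `alpha / m`, e.g. 0.05/4 = 0.0125 for the primary family of
#'   four region-of-interest tests and 0.05/10 = 0.005 for the surgical
#'   subanalysis family.
#' @examples
#' bonferroniAlpha(0.05, 4)
#' @export
bonferroniAlpha <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}
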