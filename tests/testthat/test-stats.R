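test_that("permutation test handles exchangeable and degenerate input", {
  r <- permutationTwoSample(c(1, 2, 3), c(3, 2, 1))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  same <- permutationTwoSample(c(5, 5), c(5, 5))
  expect_equal(same$p, 1)
  expect_error(permutationTwoSample(c(5, 5), c(7, 7)), "undefined")
})

test_that("exhaustive mode reproduces explicit enumeration", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  r <- permutationTwoSample(a, b)
  expect_true(r$exhaustive)
  expect_equal(r$nPermutations, 20L)
  expect_equal(r$p, exhaustivePermP(a, b))
  expect_equal(r$p, 0.1)  # only the two extreme assignments tie |t|

  set.seed(4)
  a2 <- rnorm(4); b2 <- rnorm(4) + 1
  r2 <- permutationTwoSample(a2, b2)
  expect_true(r2$exhaustive)
  expect_equal(r2$p, exhaustivePermP(a2, b2))
})

test_that("Monte-Carlo p-values approximate the exhaustive p-value", {
  set.seed(10)
  a <- rnorm(5); b <- rnorm(5) + 1.2
  pEx <- exhaustivePermP(a, b)
  B <- 20000L
  r <- permutationTwoSample(a, b, nPermutations = B, seed = 77,
                            exhaustive = FALSE)
  se <- sqrt(pEx * (1 - pEx) / B)
  expect_lt(abs(r$p - pEx), 3 * se + 2 / B)
  # determinism given the seed
  r2 <- permutationTwoSample(a, b, nPermutations = B, seed = 77,
                             exhaustive = FALSE)
  expect_identical(r$p, r2$p)
})

test_that("permutation test holds its size under the null", {
  set.seed(2024)
  rej <- 0L
  nRep <- 400L
  for (i in seq_len(nRep)) {
    x <- rnorm(12); y <- rnorm(12)
    p <- permutationTwoSample(x, y, nPermutations = 400L, seed = i,
                              exhaustive = FALSE)$p
    if (p < 0.05) rej <- rej + 1L
  }
  band <- qbinom(c(0.005, 0.995), nRep, 0.05)
  expect_gte(rej, band[1])
  expect_lte(rej, band[2])
})

test_that("Cohen's d uses the pooled sample SD and obeys the t identity", {
  expect_equal(cohensD(c(0, 2), c(1, 3)), -1 / sqrt(2))
  set.seed(5)
  a <- rnorm(8, 1); b <- rnorm(6)
  expect_equal(cohensD(a, b), cohensD(a * 10, b * 10))
  expect_equal(cohensD(a + 3, b + 3), cohensD(a, b))
  r <- permutationTwoSample(a, b, nPermutations = 50L, seed = 1,
                            exhaustive = FALSE)
  nA <- length(a); nB <- length(b)
  expect_equal(r$t, r$d * sqrt(nA * nB / (nA + nB)), tolerance = 1e-12)
  expect_error(cohensD(c(1, 1), c(1, 1)), "zero pooled")
})

test_that("Spearman correlation uses mid-ranks and the t approximation", {
  expect_equal(spearmanCorr(1:6, exp(1:6))$rho, 1)
  x <- c(1, 2, 3, 4, 5); y <- c(5, 6, 7, 8, 7)
  # mid-ranks of y written out by hand: 7 appears twice at sorted
  # positions 3 and 4 -> rank 3.5 each
  oracle <- cor(c(1, 2, 3, 4, 5), c(1, 2, 3.5, 5, 3.5))
  r <- spearmanCorr(x, y)
  expect_equal(r$rho, oracle)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(r$rho, unname(ct$estimate))
  expect_equal(spearmanCorr(x, -y)$rho, -r$rho)
  # invariance under strictly monotone transforms
  set.seed(8)
  u <- rnorm(15); v <- rnorm(15)
  expect_equal(spearmanCorr(exp(u), v)$rho, spearmanCorr(u, v)$rho)
  # p-value matches cor.test's t approximation on tied data
  expect_equal(r$p, ct$p.value, tolerance = 1e-12)
  expect_error(spearmanCorr(rep(1, 5), 1:5), "constant")
  expect_error(spearmanCorr(1:3, 3:1), "at least 4")
})

test_that("OLS adjustment matches the normal-equations oracle", {
  set.seed(12)
  d <- data.frame(x1 = rnorm(10), x2 = runif(10))
  y <- 1 + 2 * d$x1 - 0.5 * d$x2 + rnorm(10, sd = 0.3)
  fit <- olsAdjust(y, d)
  X <- cbind(1, d$x1, d$x2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(fit$coefficients), as.numeric(beta),
               tolerance = 1e-10)

  # y identical to a regressor: perfect fit (lm warns about it)
  fit2 <- suppressWarnings(olsAdjust(d$x1, d))
  expect_equal(unname(fit2$coefficients[["x1"]]), 1, tolerance = 1e-10)
  expect_equal(fit2$adjRSquared, 1, tolerance = 1e-10)

  expect_error(olsAdjust(y, cbind(d, x3 = d$x1)), "rank-deficient")
})

test_that("OLS drops incomplete records listwise and reports the count", {
  set.seed(13)
  d <- data.frame(x1 = rnorm(12))
  d$x1[c(2, 5)] <- NA
  y <- rnorm(12)
  fit <- olsAdjust(y, d)
  expect_equal(fit$nUsed, 10L)
  expect_equal(fit$nDropped, 2L)
})

test_that("Benjamini-Hochberg adjustment is the step-up procedure", {
  expect_equal(fdrBH(0.02), 0.02)
  expect_equal(fdrBH(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(fdrBH(rep(1, 5)), rep(1, 5))
  expect_error(fdrBH(c(0.5, 1.2)), "0, 1")
})

test_that("Bonferroni alpha divides the family-wise level", {
  expect_equal(bonferroniAlpha(0.05, 4), 0.0125)
  expect_equal(bonferroniAlpha(0.05, 10), 0.005)
  expect_equal(bonferroniAlpha(0.05, 1), 0.05)
})
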