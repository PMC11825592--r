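test_that("waytotal normalization divides rows by seed-region totals", {
  m <- matrix(c(0, 10, 20, 5, 0, 5, 2, 8, 0), 3, 3, byrow = TRUE)
  cn <- Connectome(m, waytotals = c(100, 50, 10))
  expect_equal(unname(normalizeByWaytotal(cn)),
               matrix(c(0, 0.1, 0.2, 0.1, 0, 0.1, 0.2, 0.8, 0), 3, 3,
                      byrow = TRUE))
  zero <- Connectome(matrix(0, 3, 3), waytotals = c(1, 2, 3))
  expect_true(all(normalizeByWaytotal(zero) == 0))
})

test_that("symmetrization averages the matrix with its transpose", {
  expect_equal(unname(edgeWeights(symmetrize(matrix(c(0, 4, 2, 0), 2, 2)))),
               matrix(c(0, 3, 3, 0), 2, 2))
  w3 <- matrix(c(0, 1, 0, 0, 0, 0, 2, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(unname(edgeWeights(symmetrize(w3))),
               matrix(c(0, 0.5, 1, 0.5, 0, 0, 1, 0, 0), 3, 3, byrow = TRUE))
  sym <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_equal(unname(edgeWeights(symmetrize(sym))), sym)
  expect_error(symmetrize(matrix(1:6, 2, 3)), "square")
})

test_that("proportional thresholding keeps the k strongest edges", {
  # full density on an all-positive matrix gives the complete graph
  w <- matrix(1, 4, 4) + diag(-1, 4)
  tn <- thresholdToDensity(ProcessedNetwork(w), 1)
  expect_identical(edgeCount(tn), 6L)
  expect_true(all(adjacency(tn)[upper.tri(w)] == 1))

  # 5 nodes, distinct weights 1..10: density 0.3 keeps the top 3
  w5 <- matrix(0, 5, 5)
  w5[upper.tri(w5)] <- c(7, 2, 9, 5, 1, 10, 4, 8, 3, 6)
  w5 <- w5 + t(w5)
  tn5 <- thresholdToDensity(ProcessedNetwork(w5), 0.3)
  expect_identical(edgeCount(tn5), 3L)
  kept <- which(adjacency(tn5) == 1 & upper.tri(w5))
  expect_setequal(w5[kept], c(10, 9, 8))

  # all-equal weights, n = 4, density 0.5: k = 3 edges picked by the
  # ascending (row, column) tie rule -> (1,2), (1,3), (1,4)
  weq <- matrix(1, 4, 4) + diag(-1, 4)
  tneq <- thresholdToDensity(ProcessedNetwork(weq), 0.5)
  expect_identical(edgeCount(tneq), 3L)
  expect_equal(unname(adjacency(tneq)[1, ]), c(0, 1, 1, 1))
  expect_equal(unname(adjacency(tneq)[2, 3:4]), c(0, 0))

  expect_error(thresholdToDensity(ProcessedNetwork(weq), 0), "density")
  expect_error(thresholdToDensity(ProcessedNetwork(weq), 1.2), "density")
})

test_that("thresholding flags unachievable densities", {
  w <- matrix(0, 5, 5)
  w[1, 2] <- w[2, 1] <- 1  # a single positive weight
  tn <- thresholdToDensity(ProcessedNetwork(w), 0.5)
  expect_identical(edgeCount(tn), 1L)
  expect_false(tn@densityAchieved)
})

test_that("density sweep enumerates exact integer percents", {
  set.seed(42)
  w <- matrix(runif(82 * 82), 82, 82); w <- (w + t(w)) / 2; diag(w) <- 0
  p <- ProcessedNetwork(w)
  sw <- densitySweep(p)
  expect_length(sw, 21L)
  expect_identical(vapply(sw, densityPercent, integer(1), USE.NAMES = FALSE),
                   20:40)
  expect_length(densitySweep(p, low = 20, high = 20), 1L)
  sw5 <- densitySweep(p, low = 20, high = 40, step = 5)
  expect_identical(vapply(sw5, densityPercent, integer(1),
                          USE.NAMES = FALSE), c(20L, 25L, 30L, 35L, 40L))
  expect_error(densitySweep(p, low = 20.5, high = 40), "integer")
})

test_that("edge counts match the closed form over all n and densities", {
  for (n in 3:20) {
    set.seed(n)
    w <- matrix(runif(n * n) + 0.01, n, n); w <- (w + t(w)) / 2; diag(w) <- 0
    p <- ProcessedNetwork(w)
    for (pct in seq(1, 100, by = 7)) {
      k <- floor(pct / 100 * n * (n - 1) / 2 + 0.5)
      expect_identical(edgeCount(thresholdToDensity(p, pct / 100)),
                       as.integer(k))
    }
  }
})

test_that("edge sets are nested and degrees monotone across the sweep", {
  set.seed(7)
  for (rep in 1:5) {
    w <- matrix(runif(20 * 20), 20, 20); w <- (w + t(w)) / 2; diag(w) <- 0
    sw <- densitySweep(ProcessedNetwork(w))
    for (d in 2:length(sw)) {
      prev <- adjacency(sw[[d - 1]]); curr <- adjacency(sw[[d]])
      expect_true(all(curr[prev == 1] == 1))  # nestedness
      expect_true(all(nodeDegree(sw[[d]]) >= nodeDegree(sw[[d - 1]])))
    }
  }
})

test_that("processing is equivariant under node relabeling", {
  cn <- generateBaseConnectome(12, baseDensity = 0.8, seed = 3)
  perm <- sample(12)
  m <- streamlineCounts(cn)[perm, perm]
  cnp <- Connectome(m, wayTotals(cn)[perm], labels = nodeLabels(cn)[perm])
  w1 <- edgeWeights(processConnectome(cn))[perm, perm]
  w2 <- edgeWeights(processConnectome(cnp))
  expect_equal(unname(w1), unname(w2))
})

test_that("fragmentation detection counts connected components", {
  full <- matrix(1, 5, 5) + diag(-1, 5)
  expect_false(isFragmented(tnFromAdj(full)))

  twoTri <- matrix(0, 6, 6)
  twoTri[cbind(c(1, 2, 3), c(2, 3, 1))] <- 1
  twoTri[cbind(c(4, 5, 6), c(5, 6, 4))] <- 1
  twoTri <- pmax(twoTri, t(twoTri))
  expect_true(isFragmented(tnFromAdj(twoTri)))

  p5 <- matrix(0, 5, 5)
  p5[cbind(1:4, 2:5)] <- 1; p5 <- pmax(p5, t(p5))
  expect_false(isFragmented(tnFromAdj(p5)))

  iso <- matrix(0, 4, 4); iso[1, 2] <- iso[2, 1] <- iso[2, 3] <-
    iso[3, 2] <- 1
  expect_true(isFragmented(tnFromAdj(iso)))  # node 4 isolated
})
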