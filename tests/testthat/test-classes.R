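test_that("Connectome validity rejects malformed inputs", {
  m <- matrix(c(0, 10, 20, 5, 0, 5, 2, 8, 0), 3, 3, byrow = TRUE)
  cn <- Connectome(m, waytotals = c(100, 50, 10), labels = c("a", "b", "c"))
  expect_s4_class(cn, "Connectome")
  expect_identical(nodeLabels(cn), c("a", "b", "c"))
  expect_identical(unname(wayTotals(cn)), c(100, 50, 10))

  expect_error(Connectome(m, waytotals = c(100, 0, 10)), "positive")
  expect_error(Connectome(m[, 1:2], waytotals = 10), "square")
  bad <- m; bad[2, 1] <- -1
  expect_error(Connectome(bad, waytotals = 10), "nonnegative")
  bad <- m; bad[1, 1] <- 3
  expect_error(Connectome(bad, waytotals = 10), "diagonal")
  expect_error(Connectome(m, waytotals = 10, labels = c("a", "a", "b")),
               "unique")
})

test_that("ProcessedNetwork and ThresholdedNetwork enforce symmetry", {
  w <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(ProcessedNetwork(w), "symmetric")
  ok <- ProcessedNetwork(matrix(c(0, 3, 3, 0), 2, 2))
  expect_identical(edgeWeights(ok)[1, 2], 3)

  a <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  tn <- new("ThresholdedNetwork", labels = c("x", "y"), adjacency = a,
            densityPercent = 100L, edgeCount = 1L, densityAchieved = TRUE)
  expect_identical(edgeCount(tn), 1L)
  expect_error(new("ThresholdedNetwork", labels = c("x", "y"), adjacency = a,
                   densityPercent = 100L, edgeCount = 2L,
                   densityAchieved = TRUE), "edgeCount")
})

test_that("show methods print a summary without error", {
  cn <- generateBaseConnectome(5, baseDensity = 1, seed = 1)
  expect_output(show(cn), "Connectome")
  p <- processConnectome(cn)
  expect_output(show(p), "ProcessedNetwork")
  tn <- thresholdToDensity(p, 0.5)
  expect_output(show(tn), "density")
  prof <- centralityProfile(p, "degree", low = 20, high = 40)
  expect_output(show(prof), "degree")
  expect_output(show(integrateAcrossDensities(prof)), "top nodes")
})
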