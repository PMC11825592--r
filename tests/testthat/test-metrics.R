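test_that("node degree counts incident edges", {
  expect_true(all(nodeDegree(tnFromAdj(matrix(0, 4, 4))) == 0))
  full <- matrix(1, 4, 4) + diag(-1, 4)
  expect_true(all(nodeDegree(tnFromAdj(full)) == 3))
  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(unname(nodeDegree(tnFromAdj(star))), c(3, 1, 1, 1))
})

test_that("betweenness follows the unnormalized undirected convention", {
  full <- matrix(1, 5, 5) + diag(-1, 5)
  expect_true(all(betweennessCentrality(tnFromAdj(full)) == 0))

  p3 <- matrix(0, 3, 3); p3[1, 2] <- p3[2, 1] <- p3[2, 3] <- p3[3, 2] <- 1
  expect_equal(unname(betweennessCentrality(tnFromAdj(p3))), c(0, 1, 0))

  c4 <- matrix(0, 4, 4)
  c4[cbind(1:4, c(2, 3, 4, 1))] <- 1; c4 <- pmax(c4, t(c4))
  expect_equal(unname(betweennessCentrality(tnFromAdj(c4))),
               rep(0.5, 4))
})

test_that("betweenness matches brute-force path enumeration on small graphs", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(4:7, 1)
    adj <- randomAdjacency(n, runif(1, 0.3, 0.9))
    expect_equal(unname(betweennessCentrality(tnFromAdj(adj))),
                 bruteForceBetweenness(adj), tolerance = 1e-12)
  }
})

test_that("integration across densities is a plain column sum", {
  prof <- new("CentralityProfile", metricName = "degree",
              values = matrix(3, 21, 4), densities = 20:40,
              labels = letters[1:4])
  expect_true(all(metricValues(integrateAcrossDensities(prof)) == 63))

  prof2 <- new("CentralityProfile", metricName = "betweenness",
               values = cbind(1:21, rep(0, 21)), densities = 20:40,
               labels = c("a", "b"))
  expect_equal(unname(metricValues(integrateAcrossDensities(prof2))),
               c(231, 0))

  one <- new("CentralityProfile", metricName = "degree",
             values = matrix(c(5, 7), 1, 2), densities = 25L,
             labels = c("a", "b"))
  expect_equal(unname(metricValues(integrateAcrossDensities(one))), c(5, 7))

  empty <- new("CentralityProfile", metricName = "degree",
               values = matrix(0, 0, 2), densities = integer(),
               labels = c("a", "b"))
  expect_error(integrateAcrossDensities(empty), "empty")
})

test_that("integrated centrality on the complete graph has closed form", {
  w <- matrix(1, 10, 10) + diag(-1, 10)
  cn <- Connectome(w * 50, waytotals = rep(1000, 10))
  # at 100% density the complete graph is retained whole: every geodesic is
  # a direct edge, so betweenness vanishes and each degree is n - 1
  sc <- subjectCentrality(cn, low = 100L, high = 100L)
  expect_true(all(metricValues(sc$betweenness) == 0))
  expect_true(all(metricValues(sc$degree) == 9))
  # the integrated value is exactly the column sum of the profile
  sc2 <- subjectCentrality(cn)
  expect_equal(metricValues(sc2$degree),
               colSums(metricValues(sc2$profiles$degree)))
  expect_equal(metricValues(sc2$betweenness),
               colSums(metricValues(sc2$profiles$betweenness)))
})

test_that("subject centrality is deterministic and permutation-equivariant", {
  cn <- generateBaseConnectome(20, baseDensity = 0.8, seed = 8)
  s1 <- subjectCentrality(cn)
  s2 <- subjectCentrality(cn)
  expect_identical(metricValues(s1$degree), metricValues(s2$degree))
  expect_identical(metricValues(s1$betweenness),
                   metricValues(s2$betweenness))
  expect_length(metricValues(s1$degree), 20L)
  expect_length(s1$fragmented, 21L)

  # relabeling the input permutes the outputs identically (ties across the
  # permutation are avoided by distinct weights with probability 1)
  perm <- sample(20)
  cnp <- Connectome(streamlineCounts(cn)[perm, perm], wayTotals(cn)[perm],
                    labels = nodeLabels(cn)[perm])
  sp <- subjectCentrality(cnp)
  expect_equal(unname(metricValues(sp$degree)),
               unname(metricValues(s1$degree)[perm]))
  expect_equal(unname(metricValues(sp$betweenness)),
               unname(metricValues(s1$betweenness)[perm]))
})

test_that("the fast sweep path equals the per-density object path", {
  cn <- generateBaseConnectome(30, baseDensity = 0.7, seed = 21)
  p <- processConnectome(cn)
  sc <- subjectCentrality(cn)
  sw <- densitySweep(p)
  degSlow <- colSums(do.call(rbind, lapply(sw, nodeDegree)))
  bcSlow <- colSums(do.call(rbind, lapply(sw, betweennessCentrality)))
  fragSlow <- vapply(sw, isFragmented, logical(1))
  expect_equal(unname(metricValues(sc$degree)), unname(degSlow))
  expect_equal(unname(metricValues(sc$betweenness)), unname(bcSlow),
               tolerance = 1e-9)
  expect_identical(unname(sc$fragmented), unname(fragSlow))
})

test_that("adding an edge never decreases any node degree", {
  set.seed(3)
  adj <- randomAdjacency(10, 0.4)
  d0 <- nodeDegree(tnFromAdj(adj))
  free <- which(adj == 0 & upper.tri(adj), arr.ind = TRUE)
  pick <- free[sample(nrow(free), 1), ]
  adj2 <- adj
  adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- 1
  expect_true(all(nodeDegree(tnFromAdj(adj2)) >= d0))
})
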