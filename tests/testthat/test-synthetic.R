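test_that("base connectome generation honours density and determinism", {
  cn <- generateBaseConnectome(3, baseDensity = 1, weightScale = 100,
                               seed = 1)
  m <- streamlineCounts(cn)
  expect_identical(dim(m), c(3L, 3L))
  expect_true(all(diag(m) == 0))
  expect_true(all(m[row(m) != col(m)] > 0))
  expect_true(all(m == round(m)))

  cn2 <- generateBaseConnectome(3, baseDensity = 1, weightScale = 100,
                                seed = 1)
  expect_identical(streamlineCounts(cn), streamlineCounts(cn2))
  expect_identical(wayTotals(cn), wayTotals(cn2))

  big <- generateBaseConnectome(82, baseDensity = 0.6, seed = 7)
  mb <- streamlineCounts(big)
  frac <- mean(mb[row(mb) != col(mb)] > 0)
  expect_lt(abs(frac - 0.6), 0.05)
  expect_true(all(wayTotals(big) > 0))
})

test_that("planting an effect scales one node's row and column only", {
  cn <- generateBaseConnectome(5, baseDensity = 0.7, seed = 2)

  ident <- plantCentralityEffect(cn, "lh_piriform", 1)
  expect_identical(streamlineCounts(ident), streamlineCounts(cn))

  boosted <- plantCentralityEffect(cn, "lh_piriform", 10)
  m0 <- streamlineCounts(cn); m1 <- streamlineCounts(boosted)
  idx <- match("lh_piriform", nodeLabels(cn))
  other <- setdiff(seq_len(5), idx)
  expect_identical(m1[other, other], m0[other, other])
  expect_equal(m1[idx, other], round(m0[idx, other] * 10))
  # planted node becomes 1st by symmetrized incident weight
  sym0 <- (m0 + t(m0)) / 2; sym1 <- (m1 + t(m1)) / 2
  expect_identical(which.max(rowSums(sym1)), which.max(rowSums(sym1))[1])
  expect_equal(unname(which.max(rowSums(sym1))), idx)
  # waytotals follow the seeding model, not the counts
  expect_identical(wayTotals(boosted), wayTotals(cn))

  expect_error(plantCentralityEffect(cn, "lh_piriform", 0), "positive")
  expect_error(plantCentralityEffect(cn, "nonexistent", 2), "unknown node")
})

test_that("cohort generation is reproducible and internally consistent", {
  spec <- cohortSpec(nNodes = 15, nGroupA = 6, nGroupB = 5,
                     nUnclassified = 1, seed = 42)
  co1 <- generateCohort(spec)
  co2 <- generateCohort(spec)
  expect_identical(clinicalTable(co1), clinicalTable(co2))
  expect_identical(lapply(connectomes(co1), streamlineCounts),
                   lapply(connectomes(co2), streamlineCounts))
  expect_identical(cohortTruth(co1), cohortTruth(co2))

  cl <- clinicalTable(co1)
  expect_identical(nrow(cl), 12L)
  expect_identical(sum(cl$drug_resistant %in% TRUE), 6L)
  expect_identical(sum(cl$drug_resistant %in% FALSE), 5L)
  expect_identical(sum(is.na(cl$drug_resistant)), 1L)
  ids <- vapply(connectomes(co1), subjectID, character(1))
  expect_identical(ids, cl$subject_id)
  expect_true(all(vapply(connectomes(co1),
                         function(x) all(streamlineCounts(x) >= 0),
                         logical(1))))
  # unclassified subjects carry surgical data only
  expect_true(all(cl$operated[is.na(cl$drug_resistant)]))
  # one classified subject has a missing duration
  expect_identical(sum(is.na(cl$duration_years)), 1L)
})

test_that("spec invariants are enforced", {
  expect_error(cohortSpec(nNodes = 2), "at least 3")
  expect_error(cohortSpec(nGroupA = 2, nGroupB = 1), "4 classified")
  expect_error(cohortSpec(baseDensity = 0.3), "baseDensity")
  expect_error(cohortSpec(durationRho = 1.5), "-1, 1")
  expect_error(cohortSpec(durationRho = 1, betaScale = 0), "infeasible")
  expect_error(cohortSpec(effectNode = "missing_node"), "not among")
})

test_that("perfect duration coupling yields near-perfect rank correlation", {
  co <- generateCohort(cohortSpec(nNodes = 12, nGroupA = 8, nGroupB = 6,
                                  nUnclassified = 0, durationRho = 1,
                                  nMissingDuration = 0L, seed = 9))
  cl <- clinicalTable(co)
  sc <- cohortTruth(co)$scales
  rho <- spearmanCorr(sc, cl$duration_years)$rho
  expect_gte(rho, 0.95)
})

test_that("default cohorts never fragment at the 20% threshold", {
  for (s in 1:3) {
    co <- generateCohort(cohortSpec(seed = s))
    cc <- cohortCentrality(co, analysisConfig(metrics = "degree", seed = s))
    expect_false(any(cc$fragmented))
  }
})
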