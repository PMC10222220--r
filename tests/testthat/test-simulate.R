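# Synthetic data generator: determinism, calibration, planted structure.

test_that("identical configuration and seed give byte-identical files", {
  cfg <- simulationConfig(nPatients = 400, seed = 99)
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- simulateJaderTables(cfg, d1)
  p2 <- simulateJaderTables(cfg, d2)
  for (f in c("drug", "reac", "demo", "truth"))
    expect_equal(unname(tools::md5sum(p1[f])), unname(tools::md5sum(p2[f])))
  # and a different seed changes the data
  p3 <- simulateJaderTables(simulationConfig(nPatients = 400, seed = 100),
                            tempfile())
  expect_false(unname(tools::md5sum(p1["drug"])) ==
                 unname(tools::md5sum(p3["drug"])))
})

test_that("with duplicate rate zero, deduplication is the identity", {
  cfg <- simulationConfig(nPatients = 300, duplicateRate = 0, seed = 7)
  paths <- simulateJaderTables(cfg, tempfile())
  drug <- suppressMessages(readJaderTable(paths["drug"], "DRUG"))
  reac <- suppressMessages(readJaderTable(paths["reac"], "REAC"))
  expect_equal(attr(deduplicateRows(drug, "DRUG"), "removed"), 0L)
  expect_equal(attr(deduplicateRows(reac, "REAC"), "removed"), 0L)
})

test_that("planted duplicates are recovered by deduplication counts", {
  cfg <- simulationConfig(nPatients = 500, duplicateRate = 0.1, seed = 8)
  paths <- simulateJaderTables(cfg, tempfile())
  drug <- suppressMessages(readJaderTable(paths["drug"], "DRUG"))
  dd <- deduplicateRows(drug, "DRUG")
  # at least the injected duplicates disappear (collisions can add more)
  expect_gte(attr(dd, "removed"), floor(nrow(drug) / 1.1 * 0.1) - 1)
  expect_equal(attr(deduplicateRows(dd, "DRUG"), "removed"), 0L)
})

test_that("baseline DILI rate is calibrated among unexposed patients", {
  cfg <- simulationConfig(nPatients = 5000, seed = 9)
  cohort <- simulateCohort(cfg)
  unexposed <- colSums(exposureMatrix(cohort)) == 0
  p_hat <- mean(diliFlag(cohort)[unexposed])
  se <- sqrt(0.08 * 0.92 / sum(unexposed))
  expect_lt(abs(p_hat - 0.08), 3 * se)
})

test_that("collinear clusters are co-prescribed with rho above 0.9", {
  cl <- list(c("Safflower", "Sappan Wood"),
             c("Pueraria Root", "Zanthoxylum Fruit", "Areca"))
  cfg <- simulationConfig(nPatients = 5000, seed = 10,
                          collinearClusters = cl)
  cohort <- simulateCohort(cfg)
  corr <- pairwiseSpearman(cohort)
  for (cluster in cl) {
    sub <- corr@rho[cluster, cluster]
    expect_true(all(sub[upper.tri(sub)] > 0.9))
  }
})

test_that("infeasible configurations fail loudly", {
  expect_error(simulationConfig(collinearClusters = list("Not A Drug")),
               "not in composition")
  expect_error(simulationConfig(plantedEffects = c("Not A Drug" = 5)),
               "unknown crude drug")
  expect_error(simulationConfig(kampoUsageProb = 1.2), "probabilities")
  expect_error(simulateIndependentExposures(100, 3, 0.2, 0.1,
                                            c(drug_099 = 2)),
               "unknown indicator")
})

test_that("truth record matches the tables after the ETL round trip", {
  cfg <- simulationConfig(nPatients = 600, seed = 12, duplicateRate = 0.05,
                          missingDemoRate = 0.05)
  paths <- simulateJaderTables(cfg, tempfile())
  truth <- attr(paths, "truth")

  drug <- suppressMessages(readJaderTable(paths["drug"], "DRUG"))
  reac <- suppressMessages(readJaderTable(paths["reac"], "REAC"))
  demo <- suppressMessages(readJaderTable(paths["demo"], "DEMO"))
  reports <- suppressMessages(buildReportDataset(
    deduplicateRows(drug, "DRUG"), deduplicateRows(reac, "REAC"), demo))
  cohort <- suppressMessages(buildPatientCohort(
    reports, readComposition(), readDiliTerms(), readAliases()))

  idx <- match(caseIds(cohort), truth$case_id)
  # DILI flag: every simulated DILI case reports a listed PT and vice versa
  expect_equal(unname(diliFlag(cohort)), truth$dili[idx])
  # exposures: recovered crude flags equal the planted exposure sets
  e <- exposureMatrix(cohort)
  for (i in sample(length(idx), 25)) {
    expect_equal(sort(rownames(e)[e[, i] == 1]),
                 sort(truth$exposure[[idx[i]]]))
  }
  # cases excluded for missing demographics were planted as missing
  excluded <- setdiff(truth$case_id[truth$case_id %in% reports$case_id],
                      caseIds(cohort))
  expect_true(all(truth$missing_demo[match(excluded, truth$case_id)]))
})
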