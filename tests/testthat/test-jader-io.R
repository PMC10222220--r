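# Reading, deduplication and dataset construction.

test_that("readJaderTable parses typed rows and preserves involvement", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(case_id = c("c1", "c2", "c3"),
                       drug_name = c("a", "b", "c"),
                       involvement = c("suspected", "concomitant",
                                       "suspected")),
            f, row.names = FALSE)
  rows <- suppressMessages(readJaderTable(f, "DRUG"))
  expect_equal(nrow(rows), 3)
  expect_equal(rows$involvement, c("suspected", "concomitant", "suspected"))
  expect_equal(unname(attr(rows, "counts")), c(3L, 3L))
})

test_that("rows that cannot be typed are rejected and counted", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(case_id = c("c1", "c2", "", "c4"),
                       drug_name = "x",
                       involvement = c("suspected", "mystery", "suspected",
                                       "被疑薬")),
            f, row.names = FALSE)
  expect_warning(rows <- suppressMessages(readJaderTable(f, "DRUG")),
                 "unknown involvement")
  expect_equal(nrow(rows), 2)           # Japanese vocabulary resolves
  expect_equal(rows$involvement, c("suspected", "suspected"))
  rej <- attr(rows, "rejected")
  expect_equal(unname(rej["unknown_involvement"]), 1L)
  expect_equal(unname(rej["empty_case_id"]), 1L)
})

test_that("DEMO parsing normalizes sex, age decades and years", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(case_id = c("c1", "c2", "c3"),
                       sex = c("男性", "Female", "不明"),
                       age_group = c("２０歳代", "90s+", "forty"),
                       reporting_year = c("2015年度", "2020", "")),
            f, row.names = FALSE)
  rows <- suppressMessages(readJaderTable(f, "DEMO"))
  expect_equal(rows$sex, c("male", "female", NA))
  expect_equal(rows$age_group, c("20s", "90s+", NA))
  expect_equal(rows$reporting_year, c(2015L, 2020L, NA))
})

test_that("a column map translates foreign headers", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(id = "c1", name = "x", role = "suspected")
  write.csv(df, f, row.names = FALSE)
  rows <- suppressMessages(readJaderTable(
    f, "DRUG", columnMap = c(case_id = "id", drug_name = "name",
                             involvement = "role")))
  expect_equal(rows$drug_name, "x")
  expect_error(suppressMessages(readJaderTable(f, "DRUG")),
               "lacks required column")
})

test_that("deduplication removes exact key tuples, keeps first occurrence", {
  expect_equal(nrow(deduplicateRows(
    data.frame(case_id = character(), pt_term = character()), "REAC")), 0)
  reac <- data.frame(case_id = c("c1", "c1"), pt_term = "Pyrexia")
  expect_equal(nrow(deduplicateRows(reac, "REAC")), 1)

  set.seed(11)
  base <- data.frame(case_id = sprintf("c%03d", sample(300, 950, TRUE)),
                     pt_term = sprintf("PT%04d", seq_len(950)))
  dup_idx <- sample(950, 50)
  rows <- rbind(base, base[dup_idx, ])[sample(1000), ]
  dd <- deduplicateRows(rows, "REAC")
  expect_equal(nrow(dd), 950)
  expect_equal(attr(dd, "removed"), 50L)
  # idempotent
  dd2 <- deduplicateRows(dd, "REAC")
  expect_equal(attr(dd2, "removed"), 0L)
  expect_equal(dd2$pt_term, dd$pt_term)
})

test_that("case-version mode keeps only each case's latest report version", {
  rows <- data.frame(case_id = c("c1", "c1", "c2"),
                     drug_name = c("a", "a", "b"),
                     involvement = "suspected",
                     report_version = c(1, 2, 1))
  dd <- deduplicateRows(rows, "DRUG", mode = "case-version")
  expect_equal(nrow(dd), 2)
  expect_equal(dd$report_version, c(2, 1))
})

test_that("report dataset is the suspected-only Cartesian join per case", {
  drug <- data.frame(case_id = "c1", drug_name = c("a", "b"),
                     involvement = "suspected")
  reac <- data.frame(case_id = "c1", pt_term = c("x", "y", "z"))
  demo <- data.frame(case_id = "c1", sex = "male", age_group = "20s",
                     reporting_year = 2020L)
  rep <- buildReportDataset(drug, reac, demo)
  expect_equal(nrow(rep), 6)
  expect_equal(rep$sex, rep("male", 6))  # demographics broadcast
})

test_that("join cardinality matches the nested-loop oracle on random fixtures", {
  set.seed(21)
  for (rep_i in 1:5) {
    drug <- data.frame(
      case_id = sprintf("c%02d", sample(20, 60, TRUE)),
      drug_name = sprintf("d%02d", sample(10, 60, TRUE)),
      involvement = sample(c("suspected", "concomitant", "interacting"),
                           60, TRUE))
    drug <- deduplicateRows(drug, "DRUG")
    reac <- data.frame(case_id = sprintf("c%02d", sample(20, 40, TRUE)),
                       pt_term = sprintf("PT%02d", sample(15, 40, TRUE)))
    reac <- deduplicateRows(reac, "REAC")
    demo <- data.frame(case_id = sprintf("c%02d", 1:15), sex = "male",
                       age_group = "50s", reporting_year = 2019L)
    got <- suppressMessages(buildReportDataset(drug, reac, demo))
    expect_equal(nrow(got), joinOracle(drug, reac, demo))
    expect_true(all(got$case_id %in% demo$case_id))
  }
})

test_that("patient dataset collapses flags by OR and excludes missing demographics", {
  paths <- writeTinyTables()
  drug <- suppressMessages(readJaderTable(paths["drug"], "DRUG"))
  reac <- suppressMessages(readJaderTable(paths["reac"], "REAC"))
  demo <- suppressMessages(readJaderTable(paths["demo"], "DEMO"))
  reports <- suppressMessages(buildReportDataset(
    deduplicateRows(drug, "DRUG"), deduplicateRows(reac, "REAC"), demo))
  cohort <- suppressMessages(buildPatientCohort(
    reports, smallComposition(), smallTermList()))

  # c4 has missing sex -> excluded; c1..c3 remain
  expect_equal(sort(caseIds(cohort)), c("c1", "c2", "c3"))
  expect_equal(S4Vectors::metadata(cohort)$nExcludedMissingDemo, 1L)
  # c1: reports on DILI PT and Pyrexia -> OR gives TRUE
  expect_true(diliFlag(cohort)[caseIds(cohort) == "c1"])
  expect_false(diliFlag(cohort)[caseIds(cohort) == "c3"])
  # c1 used formulaA (suspected) -> its three crude drugs flagged
  e <- exposureMatrix(cohort)
  expect_equal(sort(rownames(e)[e[, caseIds(cohort) == "c1"] == 1]),
               c("Herb One", "Herb Shared", "Herb Two"))
  # patient count equals distinct non-missing case ids (set-count oracle)
  ok_ids <- unique(reports$case_id[!is.na(reports$sex) &
                                     !is.na(reports$age_group)])
  expect_equal(ncol(cohort), length(ok_ids))
})

test_that("no non-suspected drug survives into the report dataset", {
  paths <- writeTinyTables()
  drug <- suppressMessages(readJaderTable(paths["drug"], "DRUG"))
  reac <- suppressMessages(readJaderTable(paths["reac"], "REAC"))
  demo <- suppressMessages(readJaderTable(paths["demo"], "DEMO"))
  reports <- suppressMessages(buildReportDataset(drug, reac, demo))
  # c1's concomitant aspirin must not appear
  expect_false(any(reports$case_id == "c1" & reports$drug_name == "aspirin"))
})
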