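# End-to-end pipeline: tables -> report dataset -> patient cohort -> groups
# -> signals -> volcano, with a run manifest validating the count chain.

#' Run the full signal-detection pipeline
#'
#' Orchestrates every stage: read and deduplicate the DRUG/REAC/DEMO tables,
#' build the report-based dataset, assign DILI/Kampo/crude-drug flags and
#' collapse to the patient-based cohort, merge collinear crude drugs, screen
#' every group, and write all artifacts to `outDir`:
#' `report_dataset.tsv`, `patient_dataset.tsv`, `groups.tsv`, `signals.tsv`,
#' `volcano.tsv`, `volcano.png`, `descriptive_report.json` and
#' `manifest.json` (input hashes, configuration snapshot and the row counts
#' of every construction step). If a stage fails, artifacts written so far
#' are renamed with a `.partial` suffix and the error is re-thrown naming
#' the stage.
#'
#' @param drugFile,reacFile,demoFile JADER-layout CSV paths.
#' @param outDir output directory (created if needed).
#' @param compositionFile,diliTermsFile,aliasFile mapping files (defaults:
#'   the packaged stand-ins).
#' @param columnMapFile optional YAML column map ([readColumnMap()]).
#' @param encoding input CSV encoding.
#' @param rhoThreshold,rorCut,alpha,minReports analysis thresholds (defaults
#'   are the published values: rho > 0.9, ROR > 1, p < 0.05, >= 10 reports).
#' @param flagMode group indicator mode, see [groupFlags()].
#' @param dedupMode see [deduplicateRows()].
#' @param topN adverse events to rank in the descriptive report.
#' @param plot write `volcano.png` (disable where no graphics device is
#'   wanted).
#' @return invisible list with `reports`, `cohort`, `groups`, `results`,
#'   `manifest`.
#' @export
runPipeline <- function(drugFile, reacFile, demoFile, outDir,
                        compositionFile = NULL, diliTermsFile = NULL,
                        aliasFile = NULL, columnMapFile = NULL,
                        encoding = "UTF-8", rhoThreshold = 0.9, rorCut = 1,
                        alpha = 0.05, minReports = 10,
                        flagMode = c("or", "representative"),
                        dedupMode = c("exact", "case-version"), topN = 50,
                        plot = TRUE) {
  flagMode <- match.arg(flagMode)
  dedupMode <- match.arg(dedupMode)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "setup"
  on_fail <- function(e) {
    for (f in written) if (file.exists(f))
      file.rename(f, paste0(f, ".partial"))
    .fail("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  }
  emit <- function(name) {
    written <<- c(written, file.path(outDir, name))
    file.path(outDir, name)
  }

  tryCatch({
    stage <- "read"
    cmap <- if (!is.null(columnMapFile)) readColumnMap(columnMapFile)
    drug <- readJaderTable(drugFile, "DRUG", cmap$DRUG, encoding)
    reac <- readJaderTable(reacFile, "REAC", cmap$REAC, encoding)
    demo <- readJaderTable(demoFile, "DEMO", cmap$DEMO, encoding)
    if (nrow(drug) == 0L) .fail("DRUG table is empty after parsing")
    if (nrow(reac) == 0L) .fail("REAC table is empty after parsing")
    if (nrow(demo) == 0L) .fail("DEMO table is empty after parsing")

    stage <- "deduplicate"
    drug_dd <- deduplicateRows(drug, "DRUG", dedupMode)
    reac_dd <- deduplicateRows(reac, "REAC", dedupMode)

    stage <- "report-dataset"
    reports <- buildReportDataset(drug_dd, reac_dd, demo)
    write.table(reports, emit("report_dataset.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    stage <- "flags-and-patient-dataset"
    composition <- if (is.null(compositionFile)) readComposition()
                   else readComposition(compositionFile)
    terms <- if (is.null(diliTermsFile)) readDiliTerms()
             else readDiliTerms(diliTermsFile)
    aliases <- if (is.null(aliasFile)) readAliases()
               else readAliases(aliasFile)
    cohort <- buildPatientCohort(reports, composition, terms, aliases)
    pat <- cbind(as.data.frame(SummarizedExperiment::colData(cohort)),
                 t(exposureMatrix(cohort)))
    write.table(pat, emit("patient_dataset.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)

    stage <- "grouping"
    corr <- pairwiseSpearman(cohort)
    groups <- mergeCollinear(corr, rhoThreshold)
    writeGroups(groups, emit("groups.tsv"))

    stage <- "signal"
    results <- signalTest(cohort, groups, rorCut = rorCut, alpha = alpha,
                          minReports = minReports, flagMode = flagMode)
    writeSignals(results, emit("signals.tsv"))

    stage <- "volcano"
    writeVolcano(results, emit("volcano.tsv"), alpha = alpha)
    if (plot)
      plotVolcano(results, emit("volcano.png"), alpha = alpha)

    stage <- "descriptive"
    writeDescriptiveReport(reports, cohort, emit("descriptive_report.json"),
                           topN = topN)

    stage <- "manifest"
    manifest <- list(
      inputs = lapply(
        setNames(c(drugFile, reacFile, demoFile),
                 c("drug", "reac", "demo")),
        function(f) list(path = f, md5 = unname(tools::md5sum(f)))),
      config = list(rhoThreshold = rhoThreshold, rorCut = rorCut,
                    alpha = alpha, minReports = minReports,
                    flagMode = flagMode, dedupMode = dedupMode,
                    encoding = encoding),
      counts = list(
        drug_read = unname(attr(drug, "counts")["read"]),
        drug_kept = unname(attr(drug, "counts")["kept"]),
        drug_deduplicated = nrow(drug_dd),
        reac_read = unname(attr(reac, "counts")["read"]),
        reac_kept = unname(attr(reac, "counts")["kept"]),
        reac_deduplicated = nrow(reac_dd),
        demo_kept = nrow(demo),
        report_records = nrow(reports),
        cases_in_reports = length(unique(reports$case_id)),
        cases_excluded_missing_demo =
          metadata(cohort)$nExcludedMissingDemo,
        patients = ncol(cohort),
        crude_drugs = nrow(cohort),
        groups = nGroups(groups),
        signals = sum(results$is_signal)),
      version = as.character(utils::packageVersion("KampoSignal")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
    jsonlite::write_json(manifest, emit("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(list(reports = reports, cohort = cohort, groups = groups,
                   results = results, manifest = manifest))
  }, error = on_fail)
}

#' Validate a run manifest's count chain
#'
#' Checks the internal consistency of the per-stage counts of a
#' `manifest.json`: deduplicated counts cannot exceed kept counts, the
#' patient count equals the distinct cases minus the missing-demographics
#' exclusions, and the group count cannot exceed the crude-drug count.
#'
#' @param manifest list from [runPipeline()] or parsed `manifest.json`.
#' @return `TRUE` invisibly, or an error describing the broken link.
#' @export
validateManifest <- function(manifest) {
  ct <- manifest$counts
  chk <- function(ok, what) if (!ok) .fail("manifest count chain: %s", what)
  chk(ct$drug_kept <= ct$drug_read, "drug kept > read")
  chk(ct$drug_deduplicated <= ct$drug_kept, "drug dedup > kept")
  chk(ct$reac_deduplicated <= ct$reac_kept, "reac dedup > kept")
  chk(ct$patients == ct$cases_in_reports - ct$cases_excluded_missing_demo,
      "patients != distinct cases - exclusions")
  chk(ct$groups <= ct$crude_drugs, "groups > crude drugs")
  chk(ct$signals <= ct$groups, "signals > groups")
  invisible(TRUE)
}
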