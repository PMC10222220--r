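# Descriptive tabulations: adverse-event ranking, cohort demographics,
# subcohort summaries.

#' Frequency table with half-up percentages
#'
#' Counts of a categorical vector with percentages against `denominator`
#' rounded half-up to one decimal (the convention of published frequency
#' tables).
#'
#' @param x character/factor vector.
#' @param denominator percentage denominator (default `length(x)`).
#' @param sort `"count"` (descending, ties by key) or `"key"`.
#' @return data.frame with columns `key`, `count`, `percent`.
#' @export
frequencyTable <- function(x, denominator = length(x),
                           sort = c("count", "key")) {
  sort <- match.arg(sort)
  tab <- table(x, useNA = "no")
  df <- data.frame(key = names(tab), count = as.integer(tab),
                   row.names = NULL)
  df <- if (sort == "count") df[order(-df$count, df$key), , drop = FALSE]
        else df[order(df$key), , drop = FALSE]
  df$percent <- roundHalfUp(100 * df$count / denominator, 1)
  rownames(df) <- NULL
  df
}

#' Rank adverse events by reporting times
#'
#' Preferred terms of the report-based dataset ranked by descending report
#' count, ties broken lexicographically. "Reporting times" counts every
#' (case, suspected drug, term) row, as in the top-50 table of the
#' full-scale analysis.
#'
#' @param reports report-based dataset from [buildReportDataset()], or any
#'   data.frame with a `pt_term` column.
#' @param n number of top events to return (default 50).
#' @return data.frame with columns `rank`, `pt_term`, `count`, `percent`
#'   (against all report rows).
#' @export
topAdverseEvents <- function(reports, n = 50) {
  ft <- frequencyTable(reports$pt_term, denominator = nrow(reports))
  ft <- head(ft, n)
  data.frame(rank = seq_len(nrow(ft)), pt_term = ft$key, count = ft$count,
             percent = ft$percent, row.names = NULL)
}

#' Aggregate report count over DILI preferred terms
#'
#' Sum of the counts of the frequency-table rows whose term is in the DILI
#' list. Applied to the full-scale top-50 table this reproduces the published
#' DILI aggregate (33,663 + 20,746 + 9,546 = 63,955 reports across the three
#' DILI terms in the top 50).
#'
#' @param freq data.frame with term and count columns (e.g. from
#'   [topAdverseEvents()]; the term column may be named `pt_term` or `key`).
#' @param diliTermList a [DiliTermList-class].
#' @return integer total.
#' @export
diliAggregateCount <- function(freq, diliTermList) {
  terms <- freq[[if ("pt_term" %in% names(freq)) "pt_term" else "key"]]
  sum(freq$count[assignDiliFlag(terms, diliTermList)])
}

#' Summarise a patient cohort
#'
#' Frequency/percentage tables for sex, age group, reporting year and the
#' Kampo x DILI flag combinations, with percentages against the (optionally
#' filtered) cohort size. `filter` restricts the cohort first, e.g.
#' `function(cd) cd$kampo & cd$dili` for the Kampo-user DILI subcohort.
#'
#' @param cohort a [PatientCohort-class].
#' @param filter optional predicate taking the `colData` and returning a
#'   logical vector.
#' @param topDiseases number of primary diseases to rank (when the cohort
#'   carries primary-disease data).
#' @return named list of frequency tables (`sex`, `age_group`,
#'   `reporting_year`, `flags`, and `primary_disease` if available) plus the
#'   denominator `n`.
#' @export
cohortSummary <- function(cohort, filter = NULL, topDiseases = 10) {
  cd <- SummarizedExperiment::colData(cohort)
  if (!is.null(filter)) cd <- cd[filter(cd), , drop = FALSE]
  n <- nrow(cd)
  flags <- ifelse(cd$kampo,
                  ifelse(cd$dili, "kampo+dili", "kampo"),
                  ifelse(cd$dili, "dili", "neither"))
  out <- list(
    n = n,
    sex = frequencyTable(cd$sex, n, sort = "key"),
    age_group = frequencyTable(cd$age_group, n, sort = "key"),
    reporting_year = frequencyTable(as.character(cd$reporting_year), n,
                                    sort = "key"),
    flags = frequencyTable(flags, n))
  if ("primary_disease" %in% colnames(cd)) {
    known <- cd$primary_disease[!.isMissing(cd$primary_disease)]
    out$primary_disease <- head(frequencyTable(known, length(known)),
                                topDiseases)
  } else {
    warning("no primary-disease information in this cohort", call. = FALSE)
    out$primary_disease <- data.frame(key = character(), count = integer(),
                                      percent = numeric())
  }
  out
}

#' Rank drugs used by a set of cases
#'
#' Ranking of drug names (suspected and concomitant) over the DRUG rows of
#' the given cases, as in the used-drug ranking of a subcohort. Each
#' (case, drug) pair counts once.
#'
#' @param drug deduplicated DRUG table.
#' @param case_ids cases to include.
#' @param n number of top drugs (default 20).
#' @return data.frame with columns `rank`, `drug_name`, `count`.
#' @export
rankUsedDrugs <- function(drug, case_ids, n = 20) {
  sub <- drug[drug$case_id %in% case_ids &
                drug$involvement %in% c("suspected", "concomitant"), ,
              drop = FALSE]
  sub <- sub[!duplicated(sub[c("case_id", "drug_name")]), , drop = FALSE]
  ft <- head(frequencyTable(sub$drug_name), n)
  data.frame(rank = seq_len(nrow(ft)), drug_name = ft$key, count = ft$count,
             row.names = NULL)
}

#' Write the descriptive report
#'
#' JSON file with the top adverse events, the whole-cohort summary and the
#' Kampo x DILI subcohort summary.
#'
#' @param reports report-based dataset.
#' @param cohort a [PatientCohort-class].
#' @param path output JSON path.
#' @param topN number of adverse events to rank.
#' @return the path, invisibly.
#' @export
writeDescriptiveReport <- function(reports, cohort, path, topN = 50) {
  rep <- list(
    top_adverse_events = topAdverseEvents(reports, topN),
    cohort = cohortSummary(cohort),
    kampo_dili_subcohort = suppressWarnings(
      cohortSummary(cohort, function(cd) cd$kampo & cd$dili)))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
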