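# Flag assignment: DILI flag from a preferred-term list, Kampo-medicine flag
# and crude-drug exposure flags from the composition matrix.

#' Read a DILI preferred-term list
#'
#' One preferred term per line; lines starting with `#` are comments. The
#' packaged `inst/extdata/dili_pt_terms.tsv` is a reduced synthetic stand-in
#' for a full hepatic-SMQ export (228 PTs at full scale).
#'
#' @param path file path (default: the packaged stand-in list).
#' @param sourceLabel provenance string stored with the list.
#' @return a [DiliTermList-class].
#' @export
readDiliTerms <- function(path = system.file("extdata", "dili_pt_terms.tsv",
                                             package = "KampoSignal"),
                          sourceLabel = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- stringi::stri_trim_both(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  DiliTermList(lines, sourceLabel)
}

#' Read a Kampo composition matrix
#'
#' Two-column UTF-8 TSV (`kampo_name`, `crude_name`), one constituent per
#' row. The packaged file is a reduced synthetic stand-in for the full
#' 148-medicine by 126-crude-drug table.
#'
#' @param path file path (default: the packaged stand-in matrix).
#' @return a [CompositionMatrix-class].
#' @export
readComposition <- function(path = system.file("extdata",
                                               "kampo_composition.tsv",
                                               package = "KampoSignal")) {
  df <- read.csv(path, sep = "\t", colClasses = "character",
                 fileEncoding = "UTF-8", comment.char = "#")
  CompositionMatrix(df)
}

#' Read a drug-name alias table
#'
#' Two-column UTF-8 TSV (`alias`, `kampo_name`) mapping raw brand strings as
#' they appear in DRUG tables to canonical Kampo medicine names.
#'
#' @param path file path (default: the packaged stand-in aliases).
#' @return named character vector: `names` are normalized aliases, values
#'   canonical (normalized) Kampo names.
#' @export
readAliases <- function(path = system.file("extdata", "kampo_aliases.tsv",
                                           package = "KampoSignal")) {
  df <- read.csv(path, sep = "\t", colClasses = "character",
                 fileEncoding = "UTF-8", comment.char = "#")
  stopifnot(all(c("alias", "kampo_name") %in% names(df)))
  setNames(normalizeTerm(df$kampo_name), normalizeTerm(df$alias))
}

#' Assign the DILI flag to preferred terms
#'
#' `TRUE` iff the normalized term is in the term list. Empty or missing terms
#' are `FALSE`.
#'
#' @param pt_term character vector of preferred terms.
#' @param terms a [DiliTermList-class].
#' @return logical vector.
#' @examples
#' tl <- DiliTermList(c("Hepatic function abnormal", "Liver disorder"))
#' assignDiliFlag(c("hepatic function ABNORMAL", "Pyrexia", ""), tl)
#' @export
assignDiliFlag <- function(pt_term, terms) {
  stopifnot(is(terms, "DiliTermList"))
  !.isMissing(pt_term) & normalizeTerm(pt_term) %in% terms@normalized
}

#' Resolve raw drug names to canonical Kampo medicine names
#'
#' A raw string resolves if its normalized form is a canonical Kampo name of
#' the composition matrix or a key of the alias table. Names that resolve
#' through an alias to a Kampo medicine absent from the composition trigger a
#' warning and stay unresolved.
#'
#' @param drug_name character vector of raw drug-name strings.
#' @param composition a [CompositionMatrix-class].
#' @param aliases optional named character vector from [readAliases()].
#' @return character vector of canonical Kampo names, `NA` where unresolved.
#' @export
resolveKampoName <- function(drug_name, composition, aliases = NULL) {
  norm <- normalizeTerm(drug_name)
  out <- ifelse(norm %in% kampoNames(composition), norm, NA_character_)
  if (!is.null(aliases)) {
    via <- unname(aliases[norm])
    known <- !is.na(via) & via %in% kampoNames(composition)
    orphan <- !is.na(via) & !known
    if (any(orphan))
      warning("alias resolves to Kampo medicine absent from composition: ",
              paste(unique(via[orphan]), collapse = ", "), call. = FALSE)
    out[is.na(out) & known] <- via[is.na(out) & known]
  }
  out
}

#' Assign Kampo and crude-drug flags to reports
#'
#' For each drug name that resolves to a Kampo medicine, the Kampo flag is
#' set and the crude-drug flags of its constituents are set from the
#' composition matrix; otherwise all flags are `FALSE`. By construction any
#' crude-drug flag implies the Kampo flag.
#'
#' @inheritParams resolveKampoName
#' @return list with `kampo` (logical vector) and `crude` (logical matrix,
#'   reports x crude drugs).
#' @examples
#' comp <- CompositionMatrix(data.frame(
#'   kampo_name = "shakuyakukanzoto",
#'   crude_name = c("Peony Root", "Glycyrrhiza")))
#' assignKampoCrudeFlags(c("shakuyakukanzoto", "amlodipine besilate"), comp)
#' @export
assignKampoCrudeFlags <- function(drug_name, composition, aliases = NULL) {
  resolved <- resolveKampoName(drug_name, composition, aliases)
  m <- membership(composition)
  crude <- matrix(FALSE, length(drug_name), ncol(m),
                  dimnames = list(NULL, colnames(m)))
  hit <- !is.na(resolved)
  if (any(hit)) crude[hit, ] <- m[resolved[hit], , drop = FALSE]
  list(kampo = hit, crude = crude)
}

#' Collapse per-report flags to one patient-level flag vector
#'
#' Element-wise OR over the reports of each case ("priority to applicable"):
#' a patient-level flag is `TRUE` iff it is `TRUE` on any report of the case.
#'
#' @param flags logical matrix or vector, one row/element per report.
#' @param case_id character vector of case ids, one per report.
#' @return logical matrix (or vector) with one row per distinct case, rows
#'   named by case id, in order of first appearance.
#' @examples
#' collapseFlags(c(FALSE, TRUE, FALSE), c("c1", "c1", "c2"))
#' @export
collapseFlags <- function(flags, case_id) {
  vec <- is.null(dim(flags))
  m <- if (vec) matrix(flags, ncol = 1) else as.matrix(flags)
  ids <- factor(case_id, levels = unique(case_id))
  agg <- rowsum(m + 0L, ids, reorder = FALSE) > 0L
  rownames(agg) <- levels(ids)
  if (vec) agg[, 1] else agg
}

#' Build the patient-based cohort
#'
#' Collapses the report-based dataset to one record per case: each flag (DILI,
#' Kampo, every crude drug) is the OR over the case's reports, demographics
#' are taken from the case's DEMO values, and cases with missing sex or age
#' group are excluded (the count is stored in `metadata()` together with the
#' flag sums).
#'
#' @param reports report-based dataset from [buildReportDataset()].
#' @param composition a [CompositionMatrix-class].
#' @param diliTermList a [DiliTermList-class].
#' @param aliases optional alias table from [readAliases()].
#' @return a [PatientCohort-class].
#' @export
buildPatientCohort <- function(reports, composition, diliTermList,
                               aliases = NULL) {
  if (nrow(reports) == 0L) .fail("report-based dataset is empty")
  dili <- assignDiliFlag(reports$pt_term, diliTermList)
  kc <- assignKampoCrudeFlags(reports$drug_name, composition, aliases)
  flags <- cbind(dili = dili, kampo = kc$kampo, kc$crude)
  patient <- collapseFlags(flags, reports$case_id)

  first <- !duplicated(reports$case_id)
  demo <- reports[first, intersect(names(reports),
                                   c("case_id", "sex", "age_group",
                                     "reporting_year", "primary_disease")),
                  drop = FALSE]
  stopifnot(identical(demo$case_id, rownames(patient)))

  keep <- !.isMissing(demo$sex) & !.isMissing(demo$age_group)
  nExcluded <- sum(!keep)
  if (nExcluded > 0)
    message(nExcluded, " case(s) with missing sex/age excluded from the ",
            "patient-based dataset")
  demo <- demo[keep, , drop = FALSE]
  patient <- patient[keep, , drop = FALSE]

  exposure <- t(patient[, -(1:2), drop = FALSE]) + 0L
  cd <- S4Vectors::DataFrame(
    case_id = demo$case_id, sex = demo$sex, age_group = demo$age_group,
    reporting_year = demo$reporting_year,
    dili = unname(patient[, "dili"]), kampo = unname(patient[, "kampo"]))
  if (!is.null(demo$primary_disease)) cd$primary_disease <- demo$primary_disease
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exposure = exposure), colData = cd)
  colnames(se) <- demo$case_id
  out <- new("PatientCohort", se)
  metadata(out)$nExcludedMissingDemo <- nExcluded
  metadata(out)$nReports <- nrow(reports)
  out
}
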