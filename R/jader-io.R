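# Reading JADER-layout CSV tables and constructing the report-based dataset.

# canonical columns per table kind; a column map can rename file headers
.jaderColumns <- list(
  DRUG = c("case_id", "drug_name", "involvement"),
  REAC = c("case_id", "pt_term", "outcome"),
  DEMO = c("case_id", "sex", "age_group", "reporting_year", "primary_disease"))

.jaderRequired <- list(
  DRUG = c("case_id", "drug_name", "involvement"),
  REAC = c("case_id", "pt_term"),
  DEMO = c("case_id", "sex", "age_group"))

# value vocabularies; matching is width/case-insensitive via normalizeTerm()
.involvementLevels <- list(
  suspected   = c("suspected", "suspected drug", "被疑薬"),
  concomitant = c("concomitant", "concomitant drug", "併用薬"),
  interacting = c("interacting", "interacting drug", "相互作用"))

.sexLevels <- list(male   = c("male", "m", "男性", "男"),
                   female = c("female", "f", "女性", "女"))

.mapLevels <- function(x, levels, missingValues) {
  norm <- normalizeTerm(x)
  out <- rep(NA_character_, length(x))
  for (lv in names(levels))
    out[norm %in% normalizeTerm(levels[[lv]])] <- lv
  out[.isMissing(x, missingValues)] <- NA_character_
  out
}

# "20s", "20歳代", "90s+", "90歳以上" -> decade bucket; otherwise NA
.parseAgeGroup <- function(x, missingValues) {
  norm <- normalizeTerm(x)
  out <- rep(NA_character_, length(x))
  m <- regmatches(norm, regexec("^([0-9]+)(s\\+?|歳代|歳以上)$", norm))
  hit <- lengths(m) == 3L
  dec <- vapply(m[hit], `[`, "", 2L)
  suf <- vapply(m[hit], `[`, "", 3L)
  plus <- suf %in% c("s+", "歳以上") | dec >= "90"
  out[hit] <- paste0(dec, ifelse(plus, "s+", "s"))
  out[.isMissing(x, missingValues)] <- NA_character_
  out
}

.parseYear <- function(x, missingValues) {
  digits <- gsub("[^0-9]", "", as.character(x))
  out <- suppressWarnings(as.integer(digits))
  out[.isMissing(x, missingValues)] <- NA_integer_
  out
}

#' Read one JADER-layout CSV table
#'
#' Parses a DRUG, REAC or DEMO table into typed rows. Field values are
#' normalized: involvement to `suspected`/`concomitant`/`interacting`, sex to
#' `male`/`female`, age to decade buckets (`"20s"`, ..., `"90s+"`), the
#' reporting year to an integer. Rows that cannot be typed (empty case id,
#' empty preferred term, unknown involvement category) are rejected with a
#' warning; rejection counts are attached as the `"rejected"` attribute and
#' the read/kept counts as `"counts"`.
#'
#' Real JADER distributions are CP932-encoded with Japanese headers; pass
#' `encoding = "CP932"` and a `columnMap` translating the canonical column
#' names to the file's headers (or supply the map as YAML through
#' [readColumnMap()]).
#'
#' @param path CSV file path.
#' @param table one of `"DRUG"`, `"REAC"`, `"DEMO"`.
#' @param columnMap named character vector mapping canonical column names
#'   (e.g. `case_id`) to the file's header names; `NULL` if the file already
#'   uses canonical headers.
#' @param encoding file encoding (default UTF-8; use `"CP932"` for PMDA
#'   distributions).
#' @param missingValues strings treated as missing in addition to empty cells.
#' @return data.frame of typed rows with attributes `"rejected"` (named
#'   integer vector of rejection reasons) and `"counts"` (rows read/kept).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(case_id = "c1", drug_name = "kakkonto",
#'                      involvement = "suspected"), f, row.names = FALSE)
#' readJaderTable(f, "DRUG")
#' @export
readJaderTable <- function(path, table = c("DRUG", "REAC", "DEMO"),
                           columnMap = NULL, encoding = "UTF-8",
                           missingValues = .defaultMissingValues) {
  table <- match.arg(table)
  if (!file.exists(path)) .fail("file not found: %s", path)
  raw <- tryCatch(
    read.csv(path, colClasses = "character", check.names = FALSE,
             fileEncoding = encoding),
    error = function(e) .fail("cannot read %s as %s-encoded CSV: %s",
                              path, encoding, conditionMessage(e)))
  canonical <- .jaderColumns[[table]]
  if (!is.null(columnMap)) {
    hit <- intersect(names(raw), columnMap)
    names(raw)[match(columnMap[columnMap %in% hit], names(raw))] <-
      names(columnMap)[columnMap %in% hit]
  }
  missing_cols <- setdiff(.jaderRequired[[table]], names(raw))
  if (length(missing_cols))
    .fail("%s table %s lacks required column(s): %s (check columnMap)",
          table, path, paste(missing_cols, collapse = ", "))
  for (col in setdiff(canonical, names(raw))) raw[[col]] <- NA_character_
  out <- raw[canonical]
  nRead <- nrow(out)

  rejected <- c(empty_case_id = 0L)
  bad <- .isMissing(out$case_id, missingValues)
  rejected["empty_case_id"] <- sum(bad)

  if (table == "DRUG") {
    out$involvement <- .mapLevels(out$involvement, .involvementLevels,
                                  missingValues)
    unknown <- is.na(out$involvement)
    if (any(unknown & !bad))
      warning(sum(unknown & !bad),
              " DRUG row(s) with unknown involvement category rejected",
              call. = FALSE)
    rejected["unknown_involvement"] <- sum(unknown & !bad)
    bad <- bad | unknown
  } else if (table == "REAC") {
    empty_pt <- .isMissing(out$pt_term, missingValues)
    rejected["empty_pt_term"] <- sum(empty_pt & !bad)
    bad <- bad | empty_pt
    out$outcome[.isMissing(out$outcome, missingValues)] <- NA_character_
  } else {
    out$sex <- .mapLevels(out$sex, .sexLevels, missingValues)
    out$age_group <- .parseAgeGroup(out$age_group, missingValues)
    out$reporting_year <- .parseYear(out$reporting_year, missingValues)
    out$primary_disease[.isMissing(out$primary_disease, missingValues)] <-
      NA_character_
  }
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("%s: read %d rows, kept %d (%d rejected)", table, nRead,
                  nrow(out), sum(rejected)))
  structure(out, rejected = rejected,
            counts = c(read = nRead, kept = nrow(out)))
}

#' Read a column map from a YAML file
#'
#' The map translates canonical column names to the headers used by a
#' particular JADER distribution, so Japanese headers need no code change.
#' The YAML holds one block per table kind, e.g.
#' `DRUG: {case_id: "識別番号", drug_name: "医薬品（一般名名称）", ...}`.
#'
#' @param path YAML file path.
#' @return named list of named character vectors, one per table kind.
#' @export
readColumnMap <- function(path) {
  m <- yaml::read_yaml(path)
  lapply(m, function(x) unlist(x))
}

#' Remove exact duplicate rows from a DRUG or REAC table
#'
#' Duplicates are exact tuples on the identifying key: `(case_id, drug_name,
#' involvement)` for DRUG and `(case_id, pt_term)` for REAC. The first
#' occurrence is kept, so output order is deterministic. With
#' `mode = "case-version"` and a `report_version` column present, only rows
#' of each case's highest report version are kept before exact
#' deduplication (an opt-in approximation of version-aware cleaning of real
#' JADER extracts).
#'
#' @param rows data.frame from [readJaderTable()].
#' @param table `"DRUG"` or `"REAC"` (determines the key).
#' @param mode `"exact"` (default) or `"case-version"`.
#' @return the deduplicated data.frame; the number of removed rows is
#'   attached as attribute `"removed"`.
#' @examples
#' reac <- data.frame(case_id = c("c1", "c1"), pt_term = "Pyrexia")
#' nrow(deduplicateRows(reac, "REAC"))  # 1
#' @export
deduplicateRows <- function(rows, table = c("DRUG", "REAC"),
                            mode = c("exact", "case-version")) {
  table <- match.arg(table)
  mode <- match.arg(mode)
  n0 <- nrow(rows)
  if (mode == "case-version" && "report_version" %in% names(rows)) {
    v <- suppressWarnings(as.numeric(rows$report_version))
    v[is.na(v)] <- -Inf
    vmax <- tapply(v, rows$case_id, max)
    rows <- rows[v == vmax[rows$case_id], , drop = FALSE]
  }
  key_cols <- if (table == "DRUG") c("case_id", "drug_name", "involvement")
              else c("case_id", "pt_term")
  key <- do.call(paste, c(rows[key_cols], sep = "\r"))
  out <- rows[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, removed = n0 - nrow(out))
}

#' Build the report-based dataset
#'
#' Inner join of the suspected-drug rows of DRUG with REAC and DEMO on the
#' case id: one row per (case, suspected drug, preferred term), demographics
#' broadcast to every row. Cases present in DRUG/REAC but absent from DEMO
#' are excluded and counted. Rows are ordered by (case_id, drug_name,
#' pt_term) for deterministic output.
#'
#' @param drug,reac,demo deduplicated tables from [readJaderTable()] /
#'   [deduplicateRows()].
#' @return data.frame with columns case_id, drug_name, pt_term, sex,
#'   age_group, reporting_year (and primary_disease when present), plus a
#'   `"counts"` attribute with the row counts at each construction step.
#' @examples
#' drug <- data.frame(case_id = "c1", drug_name = c("a", "b"),
#'                    involvement = "suspected")
#' reac <- data.frame(case_id = "c1", pt_term = c("x", "y", "z"))
#' demo <- data.frame(case_id = "c1", sex = "male", age_group = "20s",
#'                    reporting_year = 2020L)
#' nrow(buildReportDataset(drug, reac, demo))  # 2 drugs x 3 terms = 6
#' @export
buildReportDataset <- function(drug, reac, demo) {
  suspected <- drug[drug$involvement == "suspected",
                    c("case_id", "drug_name"), drop = FALSE]
  dr <- merge(suspected, reac[c("case_id", "pt_term")], by = "case_id")
  in_demo <- unique(dr$case_id) %in% demo$case_id
  n_missing_demo <- sum(!in_demo)
  demo_cols <- intersect(names(demo),
                         c("case_id", "sex", "age_group", "reporting_year",
                           "primary_disease"))
  out <- merge(dr, demo[demo_cols], by = "case_id")
  out <- out[order(out$case_id, out$drug_name, out$pt_term, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  if (n_missing_demo > 0)
    message(n_missing_demo, " case(s) without DEMO row excluded")
  structure(out, counts = c(
    suspected_drug_rows = nrow(suspected),
    drug_reac_rows = nrow(dr),
    cases_missing_demo = n_missing_demo,
    report_records = nrow(out)))
}
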