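#' DILI preferred-term list
#'
#' A set of MedDRA preferred terms (PTs) that define drug-induced liver
#' injury. Terms are matched after [normalizeTerm()] normalization, so case
#' and character-width variants compare equal. In the full-scale analysis the
#' list is the union of the hepatic SMQs exported from MedDRA/J (228 PTs);
#' the package ships a reduced synthetic stand-in under
#' `inst/extdata/dili_pt_terms.tsv` into which users can drop a full SMQ
#' export.
#'
#' @slot terms character, the preferred terms as supplied.
#' @slot normalized character, normalized terms (unique), used for matching.
#' @slot sourceLabel single string describing provenance (e.g. SMQ names).
#' @export
setClass("DiliTermList",
  slots = c(terms = "character", normalized = "character",
            sourceLabel = "character"))

setValidity("DiliTermList", function(object) {
  if (length(object@terms) == 0L) return("term list is empty")
  if (anyDuplicated(object@normalized))
    return("terms are not unique after normalization")
  TRUE
})

#' @describeIn DiliTermList-class Construct a term list from a character
#'   vector; duplicates after normalization are dropped with a message.
#' @param terms character vector of preferred terms.
#' @param sourceLabel single string describing where the terms come from.
#' @return a `DiliTermList`.
#' @examples
#' DiliTermList(c("Hepatic function abnormal", "Liver disorder"), "example")
#' @export
DiliTermList <- function(terms, sourceLabel = "") {
  terms <- terms[!.isMissing(terms)]
  norm <- normalizeTerm(terms)
  keep <- !duplicated(norm)
  if (any(!keep))
    message(sum(!keep), " duplicate term(s) dropped after normalization")
  new("DiliTermList", terms = terms[keep], normalized = norm[keep],
      sourceLabel = as.character(sourceLabel)[1])
}

#' Kampo medicine composition matrix
#'
#' Boolean membership matrix mapping each Kampo medicine (rows) to the crude
#' drugs it contains (columns). The full-scale instance covers 148 medicines
#' by 126 crude drugs; the packaged `inst/extdata/kampo_composition.tsv` is a
#' reduced stand-in. The manufacturer-priority rules by which a composition
#' file is curated are provenance of the data file, not computed here.
#'
#' @slot membership logical matrix, `rownames` = Kampo names (normalized),
#'   `colnames` = crude-drug names; each row has at least one `TRUE`.
#' @export
setClass("CompositionMatrix", slots = c(membership = "matrix"))

setValidity("CompositionMatrix", function(object) {
  m <- object@membership
  if (!is.logical(m)) return("membership must be a logical matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("membership must have Kampo row names and crude-drug column names")
  if (anyDuplicated(rownames(m))) return("duplicated Kampo names")
  if (anyDuplicated(colnames(m))) return("duplicated crude-drug names")
  if (nrow(m) > 0 && any(rowSums(m) == 0))
    return("every Kampo medicine must contain at least one crude drug")
  TRUE
})

#' @describeIn CompositionMatrix-class Construct from a two-column
#'   data.frame of (kampo_name, crude_name) pairs or a logical matrix.
#' @param x data.frame with columns `kampo_name` and `crude_name`, or a
#'   logical matrix with dimnames.
#' @return a `CompositionMatrix`.
#' @examples
#' CompositionMatrix(data.frame(kampo_name = "shakuyakukanzoto",
#'                              crude_name = c("Peony Root", "Glycyrrhiza")))
#' @export
CompositionMatrix <- function(x) {
  if (is.matrix(x)) return(new("CompositionMatrix", membership = x))
  stopifnot(all(c("kampo_name", "crude_name") %in% names(x)))
  kampo <- normalizeTerm(x$kampo_name)
  crude <- as.character(x$crude_name)
  m <- table(kampo, crude) > 0
  m <- matrix(m, nrow(m), ncol(m), dimnames = dimnames(m))
  new("CompositionMatrix", membership = m)
}

#' Patient-based cohort
#'
#' One column per case (patient), holding the binary crude-drug exposure
#' matrix as the `"exposure"` assay (crude drugs x patients) and per-patient
#' demographics plus the OR-collapsed `dili` and `kampo` flags in
#' `colData()`. Cases with missing sex or age group are excluded at
#' construction; the exclusion count is kept in `metadata()`.
#'
#' @export
setClass("PatientCohort", contains = "SummarizedExperiment")

setValidity("PatientCohort", function(object) {
  if (!"exposure" %in% SummarizedExperiment::assayNames(object))
    return("missing 'exposure' assay")
  e <- SummarizedExperiment::assay(object, "exposure")
  if (!all(e %in% c(0L, 1L))) return("exposure assay must be binary 0/1")
  need <- c("case_id", "sex", "age_group", "reporting_year", "dili", "kampo")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss)) return(paste("missing colData column(s):",
                                 paste(miss, collapse = ", ")))
  cd <- SummarizedExperiment::colData(object)
  if (anyDuplicated(cd$case_id)) return("case_id not unique")
  if (any(.isMissing(cd$sex)) || any(.isMissing(cd$age_group)))
    return("cohort contains cases with missing sex or age group")
  TRUE
})

#' Pairwise correlation of patient-level exposure flags
#'
#' Pairwise Spearman correlation of the 0/1 crude-drug indicators (equal to
#' the Pearson/phi coefficient for binary vectors) plus each indicator's
#' correlation with the DILI outcome. Constant indicators have undefined
#' correlation and are recorded in `@constant`.
#'
#' @slot rho symmetric numeric matrix of pairwise correlations (diagonal 1;
#'   `NA` where undefined).
#' @slot outcomeRho named numeric, correlation of each indicator with the
#'   DILI flag.
#' @slot constant character, names of constant (all-0 or all-1) indicators.
#' @export
setClass("FlagCorrelation",
  slots = c(rho = "matrix", outcomeRho = "numeric", constant = "character"))

setValidity("FlagCorrelation", function(object) {
  r <- object@rho
  if (nrow(r) != ncol(r)) return("rho must be square")
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) return("|rho| must be <= 1")
  if (!isTRUE(all.equal(r, t(r), check.attributes = FALSE)))
    return("rho must be symmetric")
  TRUE
})

#' Crude-drug collinearity groups
#'
#' Partition of the (non-constant) crude-drug indicators into groups, the
#' connected components of the graph with an edge wherever pairwise Spearman
#' rho exceeds the threshold. Each group's representative is the member with
#' the strongest correlation with the DILI outcome; the label joins members
#' in descending outcome correlation with `">"` (strict) or `"="` (tied).
#'
#' @slot members list of character vectors, ordered by descending outcome
#'   correlation.
#' @slot representative character, one name per group.
#' @slot label character, one display label per group.
#' @slot outcomeRho named numeric, outcome correlation of every member drug.
#' @slot excluded character, constant indicators left out of the partition.
#' @slot threshold the rho threshold used.
#' @export
setClass("CrudeDrugGroups",
  slots = c(members = "list", representative = "character",
            label = "character", outcomeRho = "numeric",
            excluded = "character", threshold = "numeric"))

setValidity("CrudeDrugGroups", function(object) {
  if (length(object@members) != length(object@representative) ||
      length(object@members) != length(object@label))
    return("members, representative and label lengths differ")
  all_members <- unlist(object@members)
  if (anyDuplicated(all_members))
    return("a crude drug appears in more than one group")
  ok <- mapply(function(m, r) r %in% m, object@members, object@representative)
  if (length(ok) && !all(ok)) return("representative not among group members")
  TRUE
})

#' Per-group DILI signal results
#'
#' One row per crude-drug group: the 2x2 contingency counts against the DILI
#' flag, the Haldane-Anscombe corrected reporting odds ratio with Wald 95\%
#' confidence interval, the two-sided Fisher exact p value (raw counts), the
#' report count `a + b`, the three-part signal verdict, and the volcano-plot
#' coordinates. Extends `DFrame`; thresholds used are kept in `metadata()`.
#'
#' @export
setClass("SignalResults", contains = "DFrame")

#' Synthetic JADER simulation configuration
#'
#' Ground-truth configuration for the synthetic data generator. Defaults
#' emulate the full-scale spontaneous-reporting conditions at desk scale; see
#' [simulationConfig()] for the values and their rationale.
#'
#' @slot nPatients number of cases.
#' @slot kampoUsageProb probability a case uses a Kampo medicine.
#' @slot composition a [CompositionMatrix-class].
#' @slot plantedEffects named numeric, per-crude-drug odds-ratio multipliers
#'   on the DILI outcome (names must be crude drugs of the composition).
#' @slot baselineDiliProb DILI probability with no planted exposure.
#' @slot duplicateRate fraction of DRUG/REAC rows duplicated verbatim.
#' @slot missingDemoRate fraction of cases with missing sex or age group.
#' @slot collinearClusters list of character vectors; members of a cluster
#'   are co-prescribed (any member exposed implies all), forcing rho = 1.
#' @slot seed integer random seed; a fixed seed gives byte-identical output.
#' @slot yearRange two integers, inclusive reporting fiscal-year range.
#' @slot maleProb probability a case is male.
#' @slot ageWeights named numeric, sampling weights over age decades.
#' @slot fillerDrugs non-Kampo drug-name vocabulary.
#' @slot fillerPtTerms non-DILI preferred-term vocabulary.
#' @slot diliPtTerms DILI preferred-term vocabulary emitted for DILI cases.
#' @slot primaryDiseases primary-disease vocabulary planted in DEMO.
#' @slot aliasRate probability a Kampo DRUG row uses a brand alias instead of
#'   the canonical name (exercises the alias resolver).
#' @export
setClass("SimulationConfig",
  slots = c(nPatients = "integer", kampoUsageProb = "numeric",
            composition = "CompositionMatrix", plantedEffects = "numeric",
            baselineDiliProb = "numeric", duplicateRate = "numeric",
            missingDemoRate = "numeric", collinearClusters = "list",
            seed = "integer", yearRange = "integer", maleProb = "numeric",
            ageWeights = "numeric", fillerDrugs = "character",
            fillerPtTerms = "character", diliPtTerms = "character",
            primaryDiseases = "character", aliasRate = "numeric"))

setValidity("SimulationConfig", function(object) {
  probs <- c(object@kampoUsageProb, object@baselineDiliProb,
             object@duplicateRate, object@missingDemoRate, object@aliasRate)
  if (any(probs < 0 | probs > 1)) return("probabilities must lie in [0, 1]")
  if (object@nPatients < 1L) return("nPatients must be positive")
  if (any(object@plantedEffects <= 0)) return("planted odds ratios must be > 0")
  crude <- colnames(object@composition@membership)
  bad <- setdiff(names(object@plantedEffects), crude)
  if (length(bad)) return(paste("planted effect on unknown crude drug:",
                                paste(bad, collapse = ", ")))
  badc <- setdiff(unlist(object@collinearClusters), crude)
  if (length(badc)) return(paste("collinear cluster member not in composition:",
                                 paste(badc, collapse = ", ")))
  if (length(object@yearRange) != 2L || diff(object@yearRange) < 0)
    return("yearRange must be two non-decreasing integers")
  TRUE
})
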