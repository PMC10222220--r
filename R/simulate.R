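# Synthetic JADER-shaped data generator with planted ground truth.

.defaultFillerDrugs <- c(
  "amlodipine besilate", "magnesium oxide", "loxoprofen sodium hydrate",
  "rebamipide", "acetaminophen", "etizolam", "lansoprazole",
  "l-carbocisteine", "famotidine", "mosapride citrate hydrate",
  "clarithromycin", "mecobalamin")

.defaultFillerPts <- c(
  "Interstitial lung disease", "Platelet count decreased", "Pyrexia",
  "Pneumonia", "White blood cell count decreased", "Anaemia", "Neutropenia",
  "Rash", "Diarrhoea", "Nausea", "Renal impairment", "Decreased appetite")

.defaultDiliPts <- c(
  "Hepatic function abnormal", "Liver disorder", "Drug-induced liver injury",
  "Hepatitis acute", "Hepatic failure", "Jaundice")

.defaultDiseases <- c(
  "Hypertension", "Constipation", "Hyperlipidaemia", "Insomnia",
  "Diabetes mellitus", "Gastrooesophageal reflux disease", "Asthma",
  "Obesity", "Depression", "Dyslipidaemia")

# age-decade sampling weights shaped like the full-scale cohort (mass at
# 60s/70s)
.defaultAgeWeights <- c("0s" = 0.03, "10s" = 0.03, "20s" = 0.06, "30s" = 0.08,
                        "40s" = 0.11, "50s" = 0.14, "60s" = 0.22,
                        "70s" = 0.25, "80s" = 0.06, "90s+" = 0.02)

#' Build a synthetic-data configuration
#'
#' Defaults are the desk-scale study conditions used throughout the test
#' suite: 20,000 cases; sex ratio 51.1/48.9 and age mass at the 60s/70s
#' decades as in the full-scale patient dataset; reporting years 2004-2021;
#' baseline DILI probability 0.08 (the full-scale patient-level DILI
#' prevalence); Kampo usage probability 0.15 (scaled up from the full-scale
#' 0.9\% so that desk-scale 2x2 tables keep exposed counts comparable to the
#' full-scale absolute numbers; see the methods vignette); small duplicate
#' and missing-demographics rates exercising the cleaning stages.
#'
#' @param nPatients number of cases.
#' @param kampoUsageProb probability a case uses one Kampo medicine.
#' @param composition a [CompositionMatrix-class] (default: the packaged
#'   stand-in).
#' @param plantedEffects named numeric of per-crude-drug odds-ratio
#'   multipliers on DILI (empty = null data).
#' @param baselineDiliProb DILI probability with no planted exposure.
#' @param duplicateRate fraction of DRUG/REAC rows duplicated verbatim.
#' @param missingDemoRate fraction of cases with missing sex or age.
#' @param collinearClusters list of crude-drug name sets to co-prescribe.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param yearRange inclusive reporting-year range.
#' @param maleProb probability of male sex.
#' @param ageWeights named decade weights.
#' @param fillerDrugs,fillerPtTerms,diliPtTerms,primaryDiseases vocabularies.
#' @param aliasRate probability a Kampo DRUG row is written under a brand
#'   alias from the packaged alias table.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(nPatients = 20000, kampoUsageProb = 0.15,
                             composition = readComposition(),
                             plantedEffects = numeric(0),
                             baselineDiliProb = 0.08, duplicateRate = 0.02,
                             missingDemoRate = 0.03,
                             collinearClusters = list(), seed = 1,
                             yearRange = c(2004L, 2021L), maleProb = 0.511,
                             ageWeights = .defaultAgeWeights,
                             fillerDrugs = .defaultFillerDrugs,
                             fillerPtTerms = .defaultFillerPts,
                             diliPtTerms = .defaultDiliPts,
                             primaryDiseases = .defaultDiseases,
                             aliasRate = 0.3) {
  new("SimulationConfig", nPatients = as.integer(nPatients),
      kampoUsageProb = kampoUsageProb, composition = composition,
      plantedEffects = plantedEffects, baselineDiliProb = baselineDiliProb,
      duplicateRate = duplicateRate, missingDemoRate = missingDemoRate,
      collinearClusters = collinearClusters, seed = as.integer(seed),
      yearRange = as.integer(yearRange), maleProb = maleProb,
      ageWeights = ageWeights, fillerDrugs = fillerDrugs,
      fillerPtTerms = fillerPtTerms, diliPtTerms = diliPtTerms,
      primaryDiseases = primaryDiseases, aliasRate = aliasRate)
}

#' A composition matrix with one crude drug per medicine
#'
#' Convenience constructor for statistical harness runs where every
#' crude-drug indicator should be an independent exposure: medicine `i`
#' contains exactly crude drug `i`.
#'
#' @param crudeNames crude-drug names, or an integer n for `drug_1..drug_n`.
#' @return a [CompositionMatrix-class].
#' @export
identityComposition <- function(crudeNames) {
  if (is.numeric(crudeNames) && length(crudeNames) == 1L)
    crudeNames <- sprintf("drug_%03d", seq_len(crudeNames))
  m <- diag(length(crudeNames)) > 0
  dimnames(m) <- list(paste0("kampo ", crudeNames), crudeNames)
  new("CompositionMatrix", membership = m)
}

# core draws shared by simulateCohort() and simulateJaderTables(): exposures,
# outcome and demographics for every case (before ETL noise)
.simulateCore <- function(config) {
  set.seed(config@seed)
  n <- config@nPatients
  comp <- membership(config@composition)
  crude <- colnames(comp)

  sex <- ifelse(runif(n) < config@maleProb, "male", "female")
  age <- sample(names(config@ageWeights), n, replace = TRUE,
                prob = config@ageWeights)
  year <- sample(seq(config@yearRange[1], config@yearRange[2]), n,
                 replace = TRUE)
  disease <- sample(config@primaryDiseases, n, replace = TRUE)

  uses_kampo <- runif(n) < config@kampoUsageProb
  product <- rep(NA_character_, n)
  product[uses_kampo] <- rownames(comp)[sample.int(nrow(comp),
                                                   sum(uses_kampo),
                                                   replace = TRUE)]
  exposure <- matrix(FALSE, n, length(crude), dimnames = list(NULL, crude))
  exposure[uses_kampo, ] <- comp[product[uses_kampo], , drop = FALSE]

  # co-prescription: any member of a collinear cluster implies all members
  for (cl in config@collinearClusters) {
    any_member <- rowSums(exposure[, cl, drop = FALSE]) > 0
    exposure[any_member, cl] <- TRUE
  }

  eta <- qlogis(config@baselineDiliProb)
  if (length(config@plantedEffects))
    eta <- eta + as.vector(exposure[, names(config@plantedEffects),
                                    drop = FALSE] %*%
                             log(config@plantedEffects))
  dili <- runif(n) < plogis(eta)

  missing_demo <- runif(n) < config@missingDemoRate
  list(case_id = sprintf("case%06d", seq_len(n)), sex = sex, age = age,
       year = year, disease = disease, product = product,
       exposure = exposure, dili = dili, missing_demo = missing_demo)
}

#' Simulate a patient cohort directly
#'
#' Matrix-level fast path past the CSV round trip: returns the
#' [PatientCohort-class] the ETL stages would produce from the same draws,
#' with every case reporting its true exposure and outcome (duplicate and
#' missing-demographics noise are properties of the table files and are
#' applied only by [simulateJaderTables()]). Used for replicate-heavy
#' statistical checks (null calibration, planted recovery).
#'
#' @param config a [SimulationConfig-class].
#' @return a [PatientCohort-class]; the planted truth is in `metadata()`.
#' @export
simulateCohort <- function(config) {
  core <- .simulateCore(config)
  cd <- S4Vectors::DataFrame(
    case_id = core$case_id, sex = core$sex, age_group = core$age,
    reporting_year = core$year, dili = core$dili,
    kampo = !is.na(core$product), primary_disease = core$disease)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exposure = t(core$exposure) + 0L), colData = cd)
  colnames(se) <- core$case_id
  out <- new("PatientCohort", se)
  metadata(out)$nExcludedMissingDemo <- 0L
  metadata(out)$truth <- list(plantedEffects = config@plantedEffects,
                              clusters = config@collinearClusters,
                              seed = config@seed)
  out
}

#' Simulate JADER-shaped DRUG/REAC/DEMO tables
#'
#' Writes three CSV files in the canonical JADER layout plus a `truth.json`
#' ground-truth record. Each case gets a DEMO row (sex or age blanked at the
#' missing-demographics rate), DRUG rows for its Kampo medicine (suspected;
#' sometimes under a brand alias) and one to three filler drugs with mixed
#' involvement, and REAC rows carrying a DILI preferred term when the
#' outcome is DILI and filler terms otherwise. Exact duplicate rows are
#' injected into DRUG and REAC at the configured rate. Identical
#' configuration and seed give byte-identical files.
#'
#' @param config a [SimulationConfig-class].
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths, invisibly; the
#'   ground truth is also returned as attribute `"truth"`.
#' @export
simulateJaderTables <- function(config, dir) {
  core <- .simulateCore(config)
  n <- config@nPatients
  aliases <- readAliases()
  alias_of <- split(names(aliases), aliases)

  demo <- data.frame(
    case_id = core$case_id, sex = core$sex, age_group = core$age,
    reporting_year = core$year, primary_disease = core$disease)
  # blank sex or age (alternating) for cases drawn as missing
  mi <- which(core$missing_demo)
  blank_sex <- mi[seq_along(mi) %% 2L == 1L]
  blank_age <- setdiff(mi, blank_sex)
  demo$sex[blank_sex] <- ""
  demo$age_group[blank_age] <- ""

  # DRUG rows: Kampo product (suspected) + 1-3 filler drugs
  kampo_idx <- which(!is.na(core$product))
  kampo_name <- core$product[kampo_idx]
  use_alias <- runif(length(kampo_idx)) < config@aliasRate
  for (i in which(use_alias)) {
    al <- alias_of[[kampo_name[i]]]
    if (!is.null(al)) kampo_name[i] <- al[1 + (kampo_idx[i] %% length(al))]
  }
  n_filler <- sample(1:3, n, replace = TRUE)
  filler_case <- rep(seq_len(n), n_filler)
  filler <- data.frame(
    case_id = core$case_id[filler_case],
    drug_name = sample(config@fillerDrugs, length(filler_case),
                       replace = TRUE),
    involvement = sample(c("suspected", "concomitant", "interacting"),
                         length(filler_case), replace = TRUE,
                         prob = c(0.6, 0.35, 0.05)))
  drug <- rbind(
    data.frame(case_id = core$case_id[kampo_idx], drug_name = kampo_name,
               involvement = "suspected"),
    filler)
  # collision duplicates (same filler drug drawn twice for a case) are
  # removed so that injected duplicates are the only exact duplicates
  drug <- drug[!duplicated(drug), , drop = FALSE]
  drug <- drug[order(drug$case_id, drug$drug_name, drug$involvement, method = "radix"), ]

  # REAC rows: the index event plus an occasional second event
  pt <- ifelse(core$dili,
               sample(config@diliPtTerms, n, replace = TRUE),
               sample(config@fillerPtTerms, n, replace = TRUE))
  extra <- which(runif(n) < 0.2)
  reac <- data.frame(
    case_id = c(core$case_id, core$case_id[extra]),
    pt_term = c(pt, sample(config@fillerPtTerms, length(extra),
                           replace = TRUE)),
    outcome = "unknown")
  reac <- reac[!duplicated(reac[c("case_id", "pt_term")]), , drop = FALSE]
  reac <- reac[order(reac$case_id, reac$pt_term, method = "radix"), ]

  dup_inject <- function(df, rate) {
    k <- floor(nrow(df) * rate)
    if (k > 0) df <- rbind(df, df[sample.int(nrow(df), k), , drop = FALSE])
    rownames(df) <- NULL
    df
  }
  drug <- dup_inject(drug, config@duplicateRate)
  reac <- dup_inject(reac, config@duplicateRate)

  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(drug = file.path(dir, "drug.csv"),
             reac = file.path(dir, "reac.csv"),
             demo = file.path(dir, "demo.csv"),
             truth = file.path(dir, "truth.json"))
  write.csv(drug, paths["drug"], row.names = FALSE, fileEncoding = "UTF-8")
  write.csv(reac, paths["reac"], row.names = FALSE, fileEncoding = "UTF-8")
  write.csv(demo, paths["demo"], row.names = FALSE, fileEncoding = "UTF-8")

  truth <- list(
    n_patients = n,
    case_id = core$case_id,
    kampo_product = core$product,
    exposure = lapply(seq_len(n), function(i)
      colnames(core$exposure)[core$exposure[i, ]]),
    dili = core$dili,
    missing_demo = core$missing_demo,
    planted_effects = as.list(config@plantedEffects),
    collinear_clusters = config@collinearClusters,
    seed = config@seed)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  structure(invisible(paths), truth = truth)
}

#' Simulate a cohort with independent crude-drug exposures
#'
#' Statistical calibration harness: every crude-drug indicator is an
#' independent Bernoulli(`exposureProb`) exposure (no composition structure,
#' the Kampo flag is the OR of the exposures), and the DILI outcome follows
#' the same logistic model as [simulateCohort()],
#' \eqn{logit(p) = logit(baseline) + \sum_{exposed} \ln OR}. With
#' independent exposures and sparse planting the marginal reporting odds
#' ratio of a planted drug coincides with its planted odds ratio, which makes
#' this the reference configuration for null-calibration and
#' parameter-recovery checks (see the methods vignette for why dense
#' planting attenuates marginal odds ratios).
#'
#' @param nPatients number of cases.
#' @param nCrude number of independent crude-drug indicators.
#' @param exposureProb per-indicator exposure probability.
#' @param baselineDiliProb DILI probability with no exposure.
#' @param plantedEffects named numeric odds-ratio multipliers (names must be
#'   `drug_001`-style indicator names, or indices).
#' @param seed integer seed.
#' @return a [PatientCohort-class].
#' @export
simulateIndependentExposures <- function(nPatients, nCrude, exposureProb,
                                         baselineDiliProb,
                                         plantedEffects = numeric(0),
                                         seed = 1) {
  set.seed(seed)
  n <- as.integer(nPatients)
  crude <- sprintf("drug_%03d", seq_len(nCrude))
  if (is.numeric(names(plantedEffects)) || is.null(names(plantedEffects))) {
    if (length(plantedEffects))
      names(plantedEffects) <- crude[seq_along(plantedEffects)]
  }
  bad <- setdiff(names(plantedEffects), crude)
  if (length(bad)) .fail("planted effect on unknown indicator: %s",
                         paste(bad, collapse = ", "))
  exposure <- matrix(runif(n * nCrude) < exposureProb, n, nCrude,
                     dimnames = list(NULL, crude))
  eta <- qlogis(baselineDiliProb)
  if (length(plantedEffects))
    eta <- eta + as.vector(exposure[, names(plantedEffects), drop = FALSE]
                           %*% log(plantedEffects))
  dili <- runif(n) < plogis(eta)
  case_id <- sprintf("case%06d", seq_len(n))
  cd <- S4Vectors::DataFrame(
    case_id = case_id, sex = rep("female", n), age_group = rep("50s", n),
    reporting_year = rep(2020L, n), dili = dili,
    kampo = rowSums(exposure) > 0)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exposure = t(exposure) + 0L), colData = cd)
  colnames(se) <- case_id
  out <- new("PatientCohort", se)
  metadata(out)$nExcludedMissingDemo <- 0L
  metadata(out)$truth <- list(plantedEffects = plantedEffects, seed = seed,
                              exposureProb = exposureProb,
                              baselineDiliProb = baselineDiliProb)
  out
}
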