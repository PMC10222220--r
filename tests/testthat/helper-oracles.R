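# Independent brute-force oracles and tiny fixture builders. Every oracle is
# deliberately written against a different primitive than the implementation
# it checks (choose() instead of dhyper(), explicit ranks instead of the phi
# identity, nested loops instead of merge()).

# Two-sided Fisher p by complete hypergeometric enumeration from binomial
# coefficients (minimum-likelihood rule, 1 + 1e-7 relative guard).
fisherOracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; n <- m1 + m2
  if (m1 == 0 || m2 == 0 || k == 0 || k == n) return(1)
  supp <- max(0, k - m2):min(k, m1)
  prob <- choose(m1, supp) * choose(m2, k - supp) / choose(n, k)
  p_obs <- prob[supp == a]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Spearman rho from explicit mid-ranks (average ties) and the Pearson
# formula on the ranks.
spearmanRankOracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Nested-loop inner join oracle for the report dataset cardinality.
joinOracle <- function(drug, reac, demo) {
  n <- 0L
  for (i in seq_len(nrow(drug))) {
    if (drug$involvement[i] != "suspected") next
    if (!drug$case_id[i] %in% demo$case_id) next
    n <- n + sum(reac$case_id == drug$case_id[i])
  }
  n
}

# A minimal composition for unit tests: two medicines sharing one crude drug.
smallComposition <- function() {
  CompositionMatrix(data.frame(
    kampo_name = c(rep("formulaA", 3), rep("formulaB", 2)),
    crude_name = c("Herb One", "Herb Two", "Herb Shared",
                   "Herb Three", "Herb Shared")))
}

smallTermList <- function() {
  DiliTermList(c("Hepatic function abnormal", "Liver disorder",
                 "Drug-induced liver injury"), "unit test")
}

# Write a tiny consistent trio of JADER-layout CSVs and return their paths.
writeTinyTables <- function(dir = tempfile("jader")) {
  dir.create(dir)
  drug <- data.frame(
    case_id = c("c1", "c1", "c2", "c2", "c3", "c4"),
    drug_name = c("formulaA", "aspirin", "formulaB", "ibuprofen",
                  "aspirin", "formulaA"),
    involvement = c("suspected", "concomitant", "suspected", "suspected",
                    "suspected", "suspected"))
  reac <- data.frame(
    case_id = c("c1", "c1", "c2", "c3", "c4"),
    pt_term = c("Hepatic function abnormal", "Pyrexia", "Liver disorder",
                "Pyrexia", "Rash"),
    outcome = "unknown")
  demo <- data.frame(
    case_id = c("c1", "c2", "c3", "c4"),
    sex = c("male", "female", "male", ""),
    age_group = c("20s", "60s", "90s+", "40s"),
    reporting_year = c(2010L, 2015L, 2020L, 2021L))
  paths <- file.path(dir, c("drug.csv", "reac.csv", "demo.csv"))
  write.csv(drug, paths[1], row.names = FALSE)
  write.csv(reac, paths[2], row.names = FALSE)
  write.csv(demo, paths[3], row.names = FALSE)
  names(paths) <- c("drug", "reac", "demo")
  paths
}
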