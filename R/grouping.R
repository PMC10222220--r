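# Collinearity grouping of the crude-drug indicators.

#' Pairwise Spearman correlation of crude-drug indicators
#'
#' For 0/1 vectors the Spearman rank correlation equals the Pearson (phi)
#' coefficient, so correlations are computed as Pearson on the binary
#' exposure matrix (the equivalence is asserted against a rank-based oracle
#' in the test suite). Constant indicators (all 0 or all 1) have undefined
#' correlation; they are flagged, recorded in `@constant`, and later excluded
#' from merging.
#'
#' @param x a [PatientCohort-class], or a binary matrix (patients x crude
#'   drugs) when `dili` is supplied.
#' @param dili logical/binary outcome vector (only when `x` is a matrix).
#' @return a [FlagCorrelation-class].
#' @export
pairwiseSpearman <- function(x, dili = NULL) {
  if (is(x, "PatientCohort")) {
    m <- t(exposureMatrix(x))
    dili <- diliFlag(x)
  } else m <- as.matrix(x)
  if (nrow(m) < 2L) .fail("need at least 2 patients")
  stopifnot(length(dili) == nrow(m))
  storage.mode(m) <- "double"
  sds <- apply(m, 2, function(v) max(v) - min(v))
  constant <- colnames(m)[sds == 0]
  if (length(constant))
    warning("constant crude-drug indicator(s) excluded from merging: ",
            paste(constant, collapse = ", "), call. = FALSE)
  rho <- suppressWarnings(cor(m))
  diag(rho) <- ifelse(colnames(m) %in% constant, NA_real_, 1)
  outcome <- suppressWarnings(drop(cor(m, as.numeric(dili))))
  new("FlagCorrelation", rho = rho,
      outcomeRho = setNames(outcome, colnames(m)), constant = constant)
}

#' Merge collinear crude-drug indicators into groups
#'
#' Groups are the connected components of the graph on non-constant crude
#' drugs with an edge wherever pairwise rho strictly exceeds `threshold`
#' (merging is transitive). Within a group, members are ordered by
#' descending correlation with the DILI outcome, ties broken by name; the
#' representative is the first member and the label joins members with
#' `" > "` (strictly ordered outcome correlation) or `" = "` (tied). On the
#' full-scale data this step merges 126 crude drugs into 104 groups; on other
#' inputs the group count follows the data.
#'
#' @param corr a [FlagCorrelation-class] from [pairwiseSpearman()].
#' @param threshold merge when rho exceeds this value (default 0.9, strict).
#' @return a [CrudeDrugGroups-class].
#' @export
mergeCollinear <- function(corr, threshold = 0.9) {
  keep <- setdiff(colnames(corr@rho), corr@constant)
  rho <- corr@rho[keep, keep, drop = FALSE]
  adj <- !is.na(rho) & rho > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  out_rho <- corr@outcomeRho

  ids <- unique(comp[keep])  # component ids in input (column) order
  members <- vector("list", length(ids))
  labels <- reps <- character(length(ids))
  for (i in seq_along(ids)) {
    mem <- names(comp)[comp == ids[i]]
    r <- out_rho[mem]
    r[is.na(r)] <- -Inf  # outcome correlation undefined (e.g. constant DILI)
    mem <- mem[order(-r, mem)]
    r <- r[mem]
    members[[i]] <- mem
    reps[i] <- mem[1]
    if (length(mem) == 1L) labels[i] <- mem
    else {
      sep <- ifelse(abs(diff(r)) < sqrt(.Machine$double.eps), " = ", " > ")
      labels[i] <- paste0(mem[1], paste0(sep, mem[-1], collapse = ""))
    }
  }
  new("CrudeDrugGroups", members = members, representative = reps,
      label = labels, outcomeRho = out_rho[keep], excluded = corr@constant,
      threshold = threshold)
}

#' Patient-level group exposure flags
#'
#' The group indicator is the element-wise OR of its members' flags (default),
#' so a group's contingency table counts any member usage; alternatively the
#' representative member's own column can be used.
#'
#' @param cohort a [PatientCohort-class].
#' @param groups a [CrudeDrugGroups-class].
#' @param mode `"or"` (default) or `"representative"`.
#' @return logical matrix, patients x groups, columns named by group label.
#' @export
groupFlags <- function(cohort, groups, mode = c("or", "representative")) {
  mode <- match.arg(mode)
  e <- t(exposureMatrix(cohort)) > 0L
  out <- vapply(seq_len(nGroups(groups)), function(i) {
    if (mode == "representative") e[, groups@representative[i]]
    else rowSums(e[, groups@members[[i]], drop = FALSE]) > 0L
  }, logical(nrow(e)))
  colnames(out) <- groups@label
  rownames(out) <- rownames(e)
  out
}

#' Write the group table
#'
#' @param groups a [CrudeDrugGroups-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeGroups <- function(groups, path) {
  df <- data.frame(
    group_id = seq_len(nGroups(groups)),
    label = groups@label,
    representative = groups@representative,
    members = vapply(groups@members, paste, "", collapse = "; "),
    outcome_rho = vapply(groups@members, function(m)
      paste(sprintf("%.4f", groups@outcomeRho[m]), collapse = "; "), ""))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
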