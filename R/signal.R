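# Disproportionality statistics: 2x2 tables, corrected ROR, Fisher's exact
# test and the three-part signal criterion.

#' Build a 2x2 contingency table of exposure against DILI
#'
#' Cell layout: `a` exposed with DILI, `b` exposed without, `c` unexposed
#' with DILI, `d` unexposed without; `a + b + c + d` equals the number of
#' patients and `a + b` the group's report count.
#'
#' @param group_flag logical/binary exposure vector (one group), or a matrix
#'   (patients x groups) for several groups at once.
#' @param dili logical/binary outcome vector of the same length.
#' @return data.frame with columns `a`, `b`, `c`, `d`, one row per group.
#' @examples
#' buildContingency(c(1,1,1,1,1,0,0,0,0,0), c(1,1,1,0,0,1,0,0,0,0))  # 3,2,1,4
#' @export
buildContingency <- function(group_flag, dili) {
  m <- if (is.null(dim(group_flag))) cbind(group = group_flag)
       else as.matrix(group_flag)
  if (nrow(m) != length(dili))
    .fail("exposure (%d) and outcome (%d) lengths differ", nrow(m),
          length(dili))
  g <- m > 0
  y <- dili > 0
  a <- colSums(g & y)
  b <- colSums(g & !y)
  cc <- sum(y) - a
  d <- sum(!y) - b
  data.frame(group = colnames(m) %||% as.character(seq_len(ncol(m))),
             a = unname(a), b = unname(b), c = unname(cc), d = unname(d),
             row.names = NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Haldane-Anscombe corrected reporting odds ratio with 95\% CI
#'
#' Adds `correction` (default 1/2) to all four cells so the odds ratio and
#' its Wald confidence interval on the log scale stay finite with zero
#' cells:
#' \deqn{ROR = \frac{(a+\tfrac12)(d+\tfrac12)}{(b+\tfrac12)(c+\tfrac12)},
#'   \quad CI = \exp\left(\ln ROR \pm z_{0.975}
#'   \sqrt{\sum_{cell} \frac{1}{cell + \tfrac12}}\right)}
#'
#' @param a,b,c,d integer vectors of raw cell counts (recycled together).
#' @param correction value added to every cell (0 for the uncorrected ROR).
#' @param conf.level confidence level of the Wald interval.
#' @return data.frame with columns `ror`, `ci_low`, `ci_high`.
#' @examples
#' rorCorrected(10, 90, 100, 9800)
#' rorCorrected(0, 0, 5, 5)   # degenerate zero-exposure table: ROR = 1
#' @export
rorCorrected <- function(a, b, c, d, correction = 0.5, conf.level = 0.95) {
  a <- a + correction; b <- b + correction
  c <- c + correction; d <- d + correction
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf.level) / 2)
  data.frame(ror = ror, ci_low = exp(log(ror) - z * se),
             ci_high = exp(log(ror) + z * se))
}

#' Two-sided Fisher's exact test for 2x2 tables
#'
#' Exact two-sided p value on the raw integer counts by hypergeometric
#' enumeration with the minimum-likelihood rule: the p value is the sum of
#' the probabilities of all tables (with the observed margins) no more
#' likely than the observed one, using the conventional `1 + 1e-7` relative
#' guard against floating-point ties — the same convention as
#' `stats::fisher.test`, against which it is verified in the test suite.
#' Implemented directly so that tens of thousands of tables can be screened
#' quickly. An empty margin gives p = 1.
#'
#' @param a,b,c,d integer vectors of raw cell counts (recycled together).
#' @return numeric vector of two-sided p values.
#' @examples
#' fisherExact2x2(5, 0, 0, 5)   # 1/choose(10,5) * 2 = 1/126
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.integer(a), n); b <- rep_len(as.integer(b), n)
  c <- rep_len(as.integer(c), n); d <- rep_len(as.integer(d), n)
  if (any(c(a, b, c, d) < 0)) .fail("negative cell count")
  vapply(seq_len(n), function(i) {
    m1 <- a[i] + b[i]          # exposed margin
    m2 <- c[i] + d[i]          # unexposed margin
    k <- a[i] + c[i]           # outcome margin
    if (m1 == 0L || m2 == 0L || k == 0L || b[i] + d[i] == 0L) return(1)
    supp <- max(0L, k - m2):min(k, m1)
    dens <- dhyper(supp, m1, m2, k)
    min(1, sum(dens[dens <= dens[supp == a[i]] * (1 + 1e-7)]))
  }, numeric(1))
}

#' Three-part signal criterion
#'
#' A crude-drug group is a signal iff ROR > `rorCut`, Fisher p < `alpha` and
#' the report count `a + b` is at least `minReports`. Failing criteria are
#' returned as reason codes.
#'
#' @param ror,p,n_reports numeric vectors (recycled together).
#' @param rorCut ROR cut-off (default 1).
#' @param alpha significance level (default 0.05).
#' @param minReports minimum report count (default 10).
#' @return list with `is_signal` (logical) and `reasons` (character; `""`
#'   for signals, otherwise failed criteria joined with `";"`).
#' @examples
#' classifySignal(c(8.63, 50, 0.9), c(1e-20, 0.001, 0.001), c(5000, 4, 100))
#' @export
classifySignal <- function(ror, p, n_reports, rorCut = 1, alpha = 0.05,
                           minReports = 10) {
  n <- max(length(ror), length(p), length(n_reports))
  ror <- rep_len(ror, n); p <- rep_len(p, n)
  n_reports <- rep_len(n_reports, n)
  fails <- cbind(ifelse(ror <= rorCut, sprintf("ror<=%g", rorCut), NA),
                 ifelse(p >= alpha, sprintf("p>=%g", alpha), NA),
                 ifelse(n_reports < minReports,
                        sprintf("reports<%d", minReports), NA))
  reasons <- apply(fails, 1, function(r) paste(r[!is.na(r)], collapse = ";"))
  list(is_signal = reasons == "", reasons = reasons)
}

#' Screen crude-drug groups for DILI association
#'
#' Runs the full signal stage on a patient cohort: group exposure flags, 2x2
#' tables against the DILI flag, Haldane-Anscombe corrected ROR with Wald
#' 95\% CI (the exact test uses the raw counts; the correction applies to the
#' ROR and CI), two-sided Fisher exact p, report count, three-part verdict
#' and volcano coordinates. When `groups` is omitted the collinearity
#' grouping is computed first with [pairwiseSpearman()] and
#' [mergeCollinear()].
#'
#' @param cohort a [PatientCohort-class].
#' @param groups a [CrudeDrugGroups-class], or `NULL` to compute it.
#' @param rhoThreshold collinearity threshold used when `groups` is `NULL`.
#' @param rorCut,alpha,minReports signal criterion, see [classifySignal()].
#' @param flagMode group indicator mode, see [groupFlags()].
#' @param correction Haldane-Anscombe constant for ROR/CI.
#' @param pFloor floor applied to p only inside `-log10(p)` so volcano
#'   coordinates stay finite; reported p values are untouched.
#' @param debugRawCI also compute the CI from raw (uncorrected) counts in
#'   columns `ror_raw`, `ci_low_raw`, `ci_high_raw`.
#' @return a [SignalResults-class], rows ordered as the groups.
#' @export
signalTest <- function(cohort, groups = NULL, rhoThreshold = 0.9, rorCut = 1,
                       alpha = 0.05, minReports = 10,
                       flagMode = c("or", "representative"), correction = 0.5,
                       pFloor = 1e-300, debugRawCI = FALSE) {
  flagMode <- match.arg(flagMode)
  if (is.null(groups))
    groups <- mergeCollinear(pairwiseSpearman(cohort), rhoThreshold)
  gf <- groupFlags(cohort, groups, flagMode)
  tab <- buildContingency(gf, diliFlag(cohort))
  est <- rorCorrected(tab$a, tab$b, tab$c, tab$d, correction = correction)
  p <- fisherExact2x2(tab$a, tab$b, tab$c, tab$d)
  nrep <- tab$a + tab$b
  cls <- classifySignal(est$ror, p, nrep, rorCut, alpha, minReports)
  res <- S4Vectors::DataFrame(
    label = tab$group, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
    n_reports = nrep, ror = est$ror, ci_low = est$ci_low,
    ci_high = est$ci_high, p_value = p, ln_ror = log(est$ror),
    neg_log10_p = -log10(pmax(p, pFloor)), is_signal = cls$is_signal,
    reasons = cls$reasons)
  if (debugRawCI) {
    raw <- rorCorrected(tab$a, tab$b, tab$c, tab$d, correction = 0)
    res$ror_raw <- raw$ror
    res$ci_low_raw <- raw$ci_low
    res$ci_high_raw <- raw$ci_high
  }
  rownames(res) <- NULL
  out <- new("SignalResults", res)
  metadata(out)$thresholds <- list(rorCut = rorCut, alpha = alpha,
                                   minReports = minReports,
                                   rhoThreshold = groups@threshold,
                                   correction = correction)
  metadata(out)$nPatients <- ncol(cohort)
  out
}

#' Write the signal table
#'
#' Full-precision columns plus rounded display columns (`ror_display`,
#' `ci_display` to 2 decimals, half-up).
#'
#' @param results a [SignalResults-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeSignals <- function(results, path) {
  df <- as.data.frame(results)
  df$ror_display <- sprintf("%.2f", roundHalfUp(df$ror, 2))
  df$ci_display <- sprintf("%.2f-%.2f", roundHalfUp(df$ci_low, 2),
                           roundHalfUp(df$ci_high, 2))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
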