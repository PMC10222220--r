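# Access to the packaged full-scale reference tabulations (plain-text
# inputs; desk-scale runs cannot reproduce the full PMDA extract).

#' Published full-scale reference tabulations
#'
#' The package ships two small TSV files with marginal results of the
#' full-scale JADER analysis (reports April 2004 - November 2021):
#' `jaderReferenceCounts()` returns the patient-based marginal counts
#' (638,876 patients; sex, modal age decades, Kampo-use and DILI counts) and
#' `jaderReferenceTopEvents()` the top-50 adverse events of the report-based
#' dataset (N = 1,865,069) with their reporting times. They serve as inputs
#' for arithmetic cross-checks (percentages, DILI aggregate count) and as
#' format examples; they are not produced by desk-scale runs.
#'
#' @return `jaderReferenceCounts()`: data.frame with `category` and `count`;
#'   `jaderReferenceTopEvents()`: data.frame with `rank`, `pt_term`, `count`.
#' @examples
#' head(jaderReferenceTopEvents())
#' @export
jaderReferenceCounts <- function() {
  read.csv(system.file("extdata", "jader_reference_counts.tsv",
                       package = "KampoSignal"),
           sep = "\t", comment.char = "#", fileEncoding = "UTF-8")
}

#' @rdname jaderReferenceCounts
#' @export
jaderReferenceTopEvents <- function() {
  read.csv(system.file("extdata", "jader_top50_adverse_events.tsv",
                       package = "KampoSignal"),
           sep = "\t", comment.char = "#", fileEncoding = "UTF-8")
}
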