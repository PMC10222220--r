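#' Normalize a MedDRA preferred term or drug-name string for comparison
#'
#' JADER strings vary in character width (full-width vs half-width), case and
#' surrounding whitespace. Terms are compared after Unicode compatibility
#' (NFKC) normalization, which folds width variants, followed by
#' case-folding and trimming.
#'
#' @param x character vector.
#' @return character vector of the same length, normalized.
#' @examples
#' normalizeTerm(c(" Hepatic Function Abnormal ", "Ｈepatitis"))
#' @export
normalizeTerm <- function(x) {
  x <- stringi::stri_trans_nfkc(as.character(x))
  tolower(stringi::stri_trim_both(x))
}

#' Round half away from zero
#'
#' `base::round()` rounds half to even; published frequency tables use
#' conventional half-up rounding (51.094\% prints as 51.1). Used for all
#' displayed percentages.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' roundHalfUp(0.25, 1)   # 0.3, where round(0.25, 1) gives 0.2
#' @export
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

# Shared missing-value convention for JADER fields (configurable per reader).
.defaultMissingValues <- c("", "NA", "不明", "unknown", "Unknown")

.isMissing <- function(x, missingValues = .defaultMissingValues) {
  is.na(x) | stringi::stri_trim_both(as.character(x)) %in% missingValues
}

# stop() with sprintf formatting, no call in the condition
.fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
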