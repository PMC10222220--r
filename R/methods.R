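# Accessors and show() methods for the S4 containers.

#' @rdname DiliTermList-class
#' @export
setMethod("diliTerms", "DiliTermList", function(x) x@terms)

#' @rdname DiliTermList-class
#' @export
setMethod("length", "DiliTermList", function(x) length(x@terms))

setMethod("show", "DiliTermList", function(object) {
  cat("DiliTermList with", length(object@terms), "preferred terms")
  if (nzchar(object@sourceLabel)) cat(" [", object@sourceLabel, "]", sep = "")
  cat("\n  e.g.:", paste(head(object@terms, 3), collapse = "; "), "\n")
})

#' @rdname CompositionMatrix-class
#' @export
setMethod("kampoNames", "CompositionMatrix",
          function(x) rownames(x@membership))

#' @rdname CompositionMatrix-class
#' @export
setMethod("crudeNames", "CompositionMatrix",
          function(x) colnames(x@membership))

#' @rdname CompositionMatrix-class
#' @export
setMethod("membership", "CompositionMatrix", function(x) x@membership)

#' @rdname CompositionMatrix-class
#' @export
setMethod("constituents", "CompositionMatrix", function(x, kampo) {
  kampo <- normalizeTerm(kampo)
  if (!kampo %in% rownames(x@membership))
    .fail("unknown Kampo medicine: %s", kampo)
  colnames(x@membership)[x@membership[kampo, ]]
})

#' @rdname CompositionMatrix-class
#' @export
setMethod("dim", "CompositionMatrix", function(x) dim(x@membership))

setMethod("show", "CompositionMatrix", function(object) {
  d <- dim(object@membership)
  cat("CompositionMatrix:", d[1], "Kampo medicines x", d[2], "crude drugs\n")
  cat("  crude drugs per medicine:",
      paste(range(rowSums(object@membership)), collapse = "-"), "\n")
})

#' @rdname PatientCohort-class
#' @export
setMethod("exposureMatrix", "PatientCohort",
          function(x) SummarizedExperiment::assay(x, "exposure"))

#' @rdname PatientCohort-class
#' @export
setMethod("diliFlag", "PatientCohort",
          function(x) SummarizedExperiment::colData(x)$dili)

#' @rdname PatientCohort-class
#' @export
setMethod("kampoFlag", "PatientCohort",
          function(x) SummarizedExperiment::colData(x)$kampo)

#' @rdname PatientCohort-class
#' @export
setMethod("caseIds", "PatientCohort",
          function(x) SummarizedExperiment::colData(x)$case_id)

setMethod("show", "PatientCohort", function(object) {
  cat("PatientCohort:", ncol(object), "cases x", nrow(object),
      "crude-drug indicators\n")
  cat("  DILI flagged:", sum(diliFlag(object)),
      " Kampo users:", sum(kampoFlag(object)), "\n")
  excl <- metadata(object)$nExcludedMissingDemo
  if (!is.null(excl))
    cat("  cases excluded for missing sex/age:", excl, "\n")
})

#' @rdname CrudeDrugGroups-class
#' @export
setMethod("nGroups", "CrudeDrugGroups", function(x) length(x@members))

#' @rdname CrudeDrugGroups-class
#' @export
setMethod("groupLabels", "CrudeDrugGroups", function(x) x@label)

#' @rdname CrudeDrugGroups-class
#' @export
setMethod("groupMembers", "CrudeDrugGroups", function(x) {
  setNames(x@members, x@label)
})

#' @rdname CrudeDrugGroups-class
#' @export
setMethod("groupRepresentatives", "CrudeDrugGroups",
          function(x) x@representative)

setMethod("show", "CrudeDrugGroups", function(object) {
  sizes <- lengths(object@members)
  cat("CrudeDrugGroups:", sum(sizes), "crude drugs in", length(sizes),
      "groups (rho >", object@threshold, ")\n")
  merged <- object@label[sizes > 1]
  if (length(merged))
    cat("  merged:", paste(head(merged, 5), collapse = " | "),
        if (length(merged) > 5) "..." else "", "\n")
  if (length(object@excluded))
    cat("  constant indicators excluded:",
        paste(object@excluded, collapse = ", "), "\n")
})

#' @rdname SignalResults-class
#' @export
setMethod("isSignal", "SignalResults", function(x) x$is_signal)

setMethod("show", "SignalResults", function(object) {
  th <- metadata(object)$thresholds
  cat("SignalResults:", nrow(object), "crude-drug groups,",
      sum(object$is_signal), "signals\n")
  if (!is.null(th))
    cat(sprintf("  criterion: ROR > %g, Fisher p < %g, reports >= %d\n",
                th$rorCut, th$alpha, th$minReports))
  callNextMethod()
})
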