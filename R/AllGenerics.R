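#' @rdname DiliTermList-class
#' @param x an object.
#' @export
setGeneric("diliTerms", function(x) standardGeneric("diliTerms"))

#' @rdname CompositionMatrix-class
#' @export
setGeneric("kampoNames", function(x) standardGeneric("kampoNames"))

#' @rdname CompositionMatrix-class
#' @export
setGeneric("crudeNames", function(x) standardGeneric("crudeNames"))

#' @rdname CompositionMatrix-class
#' @export
setGeneric("membership", function(x) standardGeneric("membership"))

#' @rdname CompositionMatrix-class
#' @param kampo a Kampo medicine name (normalized with [normalizeTerm()]).
#' @export
setGeneric("constituents", function(x, kampo) standardGeneric("constituents"))

#' @rdname PatientCohort-class
#' @export
setGeneric("exposureMatrix", function(x) standardGeneric("exposureMatrix"))

#' @rdname PatientCohort-class
#' @export
setGeneric("diliFlag", function(x) standardGeneric("diliFlag"))

#' @rdname PatientCohort-class
#' @export
setGeneric("kampoFlag", function(x) standardGeneric("kampoFlag"))

#' @rdname PatientCohort-class
#' @export
setGeneric("caseIds", function(x) standardGeneric("caseIds"))

#' @rdname CrudeDrugGroups-class
#' @export
setGeneric("nGroups", function(x) standardGeneric("nGroups"))

#' @rdname CrudeDrugGroups-class
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname CrudeDrugGroups-class
#' @export
setGeneric("groupMembers", function(x) standardGeneric("groupMembers"))

#' @rdname CrudeDrugGroups-class
#' @export
setGeneric("groupRepresentatives",
           function(x) standardGeneric("groupRepresentatives"))

#' @rdname SignalResults-class
#' @export
setGeneric("isSignal", function(x) standardGeneric("isSignal"))
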