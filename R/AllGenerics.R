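#' @include AllClasses.R
NULL

#' @rdname PeakSet-class
#' @param x,object a `PeakSet`.
#' @export
setGeneric("peakRanges", function(x) standardGeneric("peakRanges"))

#' @rdname PeakSet-class
#' @export
setGeneric("factorName", function(x) standardGeneric("factorName"))

#' @rdname PeakSet-class
#' @export
setGeneric("genomeBuild", function(x) standardGeneric("genomeBuild"))

#' @rdname PeakSet-class
#' @export
setGeneric("peakIds", function(x) standardGeneric("peakIds"))

#' @rdname PeakSet-class
#' @export
setGeneric("peakHeights", function(x) standardGeneric("peakHeights"))

#' @rdname ProximalAssignment-class
#' @param x,object a `ProximalAssignment`.
#' @export
setGeneric("assignmentPairs", function(x) standardGeneric("assignmentPairs"))

#' @rdname ProximalAssignment-class
#' @export
setGeneric("boundGenes", function(x) standardGeneric("boundGenes"))

#' @rdname PeakSharing-class
#' @param x,object a `PeakSharing`.
#' @export
setGeneric("sharingCounts", function(x) standardGeneric("sharingCounts"))

#' @rdname PeakSharing-class
#' @export
setGeneric("sharingPairs", function(x) standardGeneric("sharingPairs"))

#' @rdname BindingClassMap-class
#' @param x,object a `BindingClassMap`.
#' @export
setGeneric("bindingClasses", function(x) standardGeneric("bindingClasses"))

#' @rdname BindingClassMap-class
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @rdname PFMotif-class
#' @param x,object a `PFMotif`.
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))

#' @rdname PFMotif-class
#' @export
setGeneric("logOddsMatrix", function(x) standardGeneric("logOddsMatrix"))

#' @rdname PFMotif-class
#' @export
setGeneric("motifConsensus", function(x) standardGeneric("motifConsensus"))

#' @rdname ConservationTable-class
#' @param x,object a `ConservationTable`.
#' @export
setGeneric("conservationSummary",
           function(x) standardGeneric("conservationSummary"))
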