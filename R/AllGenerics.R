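#' Accessors for virionPred objects
#'
#' Small generic family giving read access to the package's S4 containers
#' without touching slots directly.
#'
#' @param x An object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname accessors
#' @export
setGeneric("fScores", function(x) standardGeneric("fScores"))

#' @rdname accessors
#' @export
setGeneric("rankOrder", function(x) standardGeneric("rankOrder"))

#' @rdname accessors
#' @export
setGeneric("rankScores", function(x) standardGeneric("rankScores"))

#' @rdname accessors
#' @export
setGeneric("peakK", function(x) standardGeneric("peakK"))

#' @rdname accessors
#' @export
setGeneric("accuracies", function(x) standardGeneric("accuracies"))

#' @rdname accessors
#' @export
setGeneric("peakMetrics", function(x) standardGeneric("peakMetrics"))

#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
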