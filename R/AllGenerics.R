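#' @rdname ProteomeMatrix
#' @param object,x a `ProteomeMatrix`.
#' @export
setGeneric("abundanceScale", function(object) standardGeneric("abundanceScale"))

#' @rdname ProteomeMatrix
#' @export
setGeneric("abundanceValues", function(object) standardGeneric("abundanceValues"))

#' @rdname ReferenceIntervalSet-class
#' @param object a `ReferenceIntervalSet`.
#' @export
setGeneric("riTable", function(object) standardGeneric("riTable"))

#' @rdname OutlierCalls-class
#' @param object an `OutlierCalls`.
#' @export
setGeneric("outlierMatrix", function(object) standardGeneric("outlierMatrix"))

#' @rdname OutlierCalls-class
#' @export
setGeneric("outlierCounts", function(object) standardGeneric("outlierCounts"))

#' @rdname SubtypeResult-class
#' @param object a `SubtypeResult`.
#' @export
setGeneric("chosenK", function(object) standardGeneric("chosenK"))

#' @rdname SubtypeResult-class
#' @param k integer cluster number; defaults to `chosenK(object)`.
#' @export
setGeneric("assignments", function(object, k) standardGeneric("assignments"))

#' @rdname SubtypeResult-class
#' @export
setGeneric("consensusMatrix", function(object, k) standardGeneric("consensusMatrix"))

#' @rdname SubtypeResult-class
#' @export
setGeneric("kRange", function(object) standardGeneric("kRange"))

#' Write a result object to a tab-separated file
#'
#' Serializes the package's result types to plain TSV so that a round-trip
#' through [readReferenceIntervals()], [readOutlierCalls()],
#' [readSubtypeAssignments()] or [readAbundanceMatrix()] reproduces all
#' integer/boolean fields bit-exactly and real fields to better than 1e-12
#' relative error.
#'
#' @param object a `ProteomeMatrix`, `ReferenceIntervalSet`, `OutlierCalls`,
#'   `SubtypeResult` or data.frame.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
setGeneric("writeResults", function(object, path) standardGeneric("writeResults"))
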