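#' @rdname ReferenceIntervalSet-class
#' @export
setMethod("riTable", "ReferenceIntervalSet", function(object)
  object@intervals)

setMethod("show", "ReferenceIntervalSet", function(object) {
  ri <- object@intervals
  cat(sprintf("ReferenceIntervalSet: %d proteins (%d with a defined RI)\n",
              nrow(ri), sum(ri$defined)))
  if (length(object@params))
    cat(sprintf("  built from %s reference samples; min_ref = %s; zeros %s\n",
                object@params$n_reference_samples, object@params$min_ref,
                if (isTRUE(object@params$detected_only)) "excluded" else "included"))
  invisible(NULL)
})

#' @rdname OutlierCalls-class
#' @export
setMethod("outlierMatrix", "OutlierCalls", function(object) object@calls)

#' @rdname OutlierCalls-class
#' @export
setMethod("outlierCounts", "OutlierCalls", function(object) object@counts)

setMethod("show", "OutlierCalls", function(object) {
  cat(sprintf("OutlierCalls: %d samples x %d proteins\n",
              nrow(object@calls), ncol(object@calls)))
  cat(sprintf("  per-sample outlier count: median %.0f (range %d-%d)\n",
              stats::median(object@counts), min(object@counts),
              max(object@counts)))
  invisible(NULL)
})

#' @rdname SubtypeResult-class
#' @export
setMethod("chosenK", "SubtypeResult", function(object) object@chosenK)

#' @rdname SubtypeResult-class
#' @export
setMethod("kRange", "SubtypeResult", function(object) object@kRange)

#' @rdname SubtypeResult-class
#' @export
setMethod("assignments", "SubtypeResult", function(object, k) {
  if (missing(k)) k <- object@chosenK
  k <- as.character(k)
  if (!k %in% rownames(object@assignments))
    stop("k = ", k, " was not evaluated")
  stats::setNames(object@assignments[k, ], colnames(object@assignments))
})

#' @rdname SubtypeResult-class
#' @export
setMethod("consensusMatrix", "SubtypeResult", function(object, k) {
  if (missing(k)) k <- object@chosenK
  k <- as.character(k)
  if (!k %in% names(object@consensus))
    stop("k = ", k, " was not evaluated")
  object@consensus[[k]]
})

setMethod("show", "SubtypeResult", function(object) {
  cat(sprintf("SubtypeResult: %d items, k evaluated in %d..%d, chosen k = %d\n",
              ncol(object@assignments), min(object@kRange), max(object@kRange),
              object@chosenK))
  tab <- table(assignments(object))
  cat("  cluster sizes at chosen k: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(NULL)
})
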