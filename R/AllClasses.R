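#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

#' Anatomical regions of the stomach
#'
#' The seven anatomical regions sampled in a region-resolved mucosa cohort:
#' cardia (Ca), fundus (Fu), lesser curvature (LC), greater curvature (GC),
#' angular incisure (AI), antrum (An) and pylorus (Py).  Proteomically the
#' regions group into a proximal section (Ca, Fu, LC, GC) and a distal
#' section (AI, An, Py); see [regionSection()].
#'
#' @format Character vectors of region codes.
#' @export
STOMACH_REGIONS <- c("Ca", "Fu", "LC", "GC", "AI", "An", "Py")

#' @rdname STOMACH_REGIONS
#' @export
PROXIMAL_REGIONS <- c("Ca", "Fu", "LC", "GC")

#' @rdname STOMACH_REGIONS
#' @export
DISTAL_REGIONS <- c("AI", "An", "Py")

.ABUNDANCE_SCALES <- c("ibaq", "fot", "ifot")
.TISSUE_CLASSES <- c("N", "TNT", "T")

#' ProteomeMatrix: a protein-by-sample abundance matrix
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay,
#' \code{"abundance"}: a nonnegative protein (row) by sample (column) matrix
#' in which 0 encodes "not detected" (label-free proteomics has no separate
#' missing-value sentinel).  The \code{abundanceScale} slot records the
#' quantification scale: \code{"ibaq"} (intensity-based absolute
#' quantification), \code{"fot"} (fraction of total; columns of an unfiltered
#' matrix sum to 1) or \code{"ifot"} (FOT scaled by 1e5 for readability of
#' low-abundance proteins).
#'
#' @slot abundanceScale character(1), one of \code{"ibaq"}, \code{"fot"},
#'   \code{"ifot"}.
#'
#' @seealso [ProteomeMatrix()], [computeFOT()], [computeIFOT()]
#' @export
setClass("ProteomeMatrix",
  contains = "SummarizedExperiment",
  representation(abundanceScale = "character")
)

setValidity("ProteomeMatrix", function(object) {
  msg <- character()
  if (length(object@abundanceScale) != 1L ||
      !object@abundanceScale %in% .ABUNDANCE_SCALES) {
    msg <- c(msg, sprintf("abundanceScale must be one of %s",
                          paste(.ABUNDANCE_SCALES, collapse = ", ")))
  }
  if (!"abundance" %in% assayNames(object)) {
    msg <- c(msg, "assay 'abundance' is required")
  } else {
    a <- assay(object, "abundance")
    if (!is.numeric(a)) msg <- c(msg, "abundance assay must be numeric")
    if (anyNA(a)) msg <- c(msg, "abundance values must not be NA (0 = not detected)")
    else if (any(a < 0)) msg <- c(msg, "abundance values must be nonnegative")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "protein ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (length(msg)) msg else TRUE
})

#' ReferenceIntervalSet: per-protein reference intervals
#'
#' Per-protein percentile reference intervals (RIs) built from a normal
#' cohort.  For each protein, \code{p10} and \code{p90} are the 10th and 90th
#' percentiles of its abundance across the reference samples and the upper
#' limit is \code{upper = p90 + 3 * (p90 - p10)}.  Proteins with fewer than
#' the required number of reference values are retained with
#' \code{defined = FALSE} and never used for outlier calling.
#'
#' @slot intervals a [S4Vectors::DataFrame] with columns \code{protein_id},
#'   \code{n_ref}, \code{p10}, \code{p90}, \code{upper}, \code{defined}.
#' @slot params list of the parameters used (\code{min_ref},
#'   \code{detected_only}, reference sample count).
#'
#' @seealso [buildReferenceIntervals()], [callOutliers()]
#' @export
setClass("ReferenceIntervalSet",
  representation(intervals = "DataFrame", params = "list")
)

setValidity("ReferenceIntervalSet", function(object) {
  ri <- object@intervals
  need <- c("protein_id", "n_ref", "p10", "p90", "upper", "defined")
  if (!all(need %in% colnames(ri)))
    return(sprintf("intervals must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(ri$protein_id)) return("protein ids must be unique")
  def <- ri$defined
  if (any(def)) {
    p10 <- ri$p10[def]; p90 <- ri$p90[def]; up <- ri$upper[def]
    if (any(p10 > p90)) return("p10 must be <= p90")
    if (any(up < p90)) return("upper must be >= p90")
    if (any(abs(up - (p90 + 3 * (p90 - p10))) >
            1e-8 * pmax(1, abs(up))))
      return("upper must equal p90 + 3*(p90 - p10)")
  }
  TRUE
})

#' OutlierCalls: outlier-protein calls for query samples
#'
#' Boolean sample-by-protein matrix of outlier calls against a
#' [ReferenceIntervalSet]: a protein is an outlier in a sample when its
#' abundance is strictly greater than the RI upper limit.  \code{counts}
#' caches the per-sample number of outlier proteins.
#'
#' @slot calls logical matrix, samples x proteins.
#' @slot counts named integer vector, one entry per sample.
#'
#' @seealso [callOutliers()], [selectOutlierFeatures()]
#' @export
setClass("OutlierCalls",
  representation(calls = "matrix", counts = "integer")
)

setValidity("OutlierCalls", function(object) {
  cl <- object@calls
  if (!is.logical(cl)) return("calls must be a logical matrix")
  if (anyNA(cl)) return("calls must not contain NA")
  if (is.null(rownames(cl)) || is.null(colnames(cl)))
    return("calls must have sample rownames and protein colnames")
  cnt <- object@counts
  if (length(cnt) != nrow(cl)) return("counts must have one entry per sample")
  if (!identical(unname(as.integer(rowSums(cl))), unname(cnt)))
    return("counts must equal rowSums(calls)")
  TRUE
})

#' SubtypeResult: resampling consensus-clustering output
#'
#' Result of resampling consensus clustering over a range of cluster numbers
#' k.  For each k, \code{consensus[[as.character(k)]]} is the symmetric
#' item-by-item consensus matrix (co-clustering frequency among co-sampled
#' resamples, unit diagonal, entries in [0, 1]) and
#' \code{assignments[as.character(k), ]} the integer cluster labels from
#' average-linkage hierarchical clustering of 1 - consensus.
#'
#' @slot kRange integer vector of evaluated k.
#' @slot consensus named list of consensus matrices, one per k.
#' @slot assignments integer matrix, one row per k (rownames = k), one column
#'   per item.
#' @slot chosenK integer(1), the k selected by [chooseK()].
#' @slot seed integer(1) RNG seed used for resampling.
#' @slot params list (reps, item_frac).
#'
#' @seealso [consensusCluster()], [chooseK()], [subtypeReport()]
#' @export
setClass("SubtypeResult",
  representation(kRange = "integer", consensus = "list",
                 assignments = "matrix", chosenK = "integer",
                 seed = "integer", params = "list")
)

setValidity("SubtypeResult", function(object) {
  ks <- object@kRange
  if (!length(ks)) return("kRange must be nonempty")
  if (!identical(names(object@consensus), as.character(ks)))
    return("consensus list names must match kRange")
  for (k in as.character(ks)) {
    cm <- object@consensus[[k]]
    if (!isSymmetric(unname(cm))) return("consensus matrices must be symmetric")
    if (any(cm < 0 | cm > 1)) return("consensus entries must be in [0, 1]")
    if (any(abs(diag(cm) - 1) > 1e-12)) return("consensus diagonal must be 1")
  }
  am <- object@assignments
  if (!identical(rownames(am), as.character(ks)))
    return("assignment rows must match kRange")
  for (i in seq_along(ks)) {
    labs <- am[i, ]
    if (length(unique(labs)) != ks[i])
      return(sprintf("assignments for k=%d must form exactly %d nonempty groups",
                     ks[i], ks[i]))
  }
  if (length(object@chosenK) != 1L || !object@chosenK %in% ks)
    return("chosenK must be one of kRange")
  TRUE
})
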