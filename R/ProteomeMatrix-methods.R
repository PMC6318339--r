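#' Construct a ProteomeMatrix
#'
#' @param values nonnegative numeric matrix, proteins (rows) by samples
#'   (columns), with unique dimnames; 0 encodes "not detected".
#' @param scale abundance scale, one of `"ibaq"`, `"fot"`, `"ifot"`.
#' @param metadata optional sample metadata `data.frame` (see
#'   [readSampleMetadata()]); matched to the columns by its `sample` column
#'   and stored in `colData`.
#'
#' @return a [ProteomeMatrix-class] object.
#' @examples
#' m <- matrix(c(2, 3, 5, 7, 0, 0), nrow = 3,
#'             dimnames = list(paste0("P", 1:3), c("s1", "s2")))
#' pm <- ProteomeMatrix(m, scale = "ibaq")
#' abundanceScale(computeFOT(pm))
#' @export
ProteomeMatrix <- function(values, scale = c("ibaq", "fot", "ifot"),
                           metadata = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se_args <- list(assays = list(abundance = values))
  if (!is.null(metadata)) {
    md <- as.data.frame(metadata)
    if (!"sample" %in% colnames(md))
      stop("metadata must have a 'sample' column")
    miss <- setdiff(colnames(values), md$sample)
    if (length(miss))
      stop("samples missing from metadata: ",
           paste(utils::head(miss, 5), collapse = ", "))
    md <- md[match(colnames(values), md$sample), , drop = FALSE]
    rownames(md) <- md$sample
    se_args$colData <- S4Vectors::DataFrame(md)
  }
  se <- do.call(SummarizedExperiment, se_args)
  new("ProteomeMatrix", se, abundanceScale = scale)
}

#' @rdname ProteomeMatrix
#' @export
setMethod("abundanceScale", "ProteomeMatrix", function(object)
  object@abundanceScale)

#' @rdname ProteomeMatrix
#' @export
setMethod("abundanceValues", "ProteomeMatrix", function(object)
  assay(object, "abundance"))

setMethod("show", "ProteomeMatrix", function(object) {
  a <- assay(object, "abundance")
  cat(sprintf("ProteomeMatrix: %d proteins x %d samples [scale: %s]\n",
              nrow(a), ncol(a), object@abundanceScale))
  cat(sprintf("  detected entries: %.1f%%\n", 100 * mean(a > 0)))
  if (ncol(colData(object)) > 0 && "region" %in% colnames(colData(object))) {
    tab <- table(colData(object)$region)
    cat("  samples per region: ",
        paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(NULL)
})

# swap the scale tag after a normalization step (internal)
.retag <- function(pm, values, scale) {
  out <- pm
  assay(out, "abundance") <- values
  out@abundanceScale <- scale
  validObject(out)
  out
}
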