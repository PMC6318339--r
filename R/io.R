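#' Derive the stomach section from a region code
#'
#' The seven anatomical regions group proteomically into two sections:
#' proximal (Ca, Fu, LC, GC) and distal (AI, An, Py).  The derivation is a
#' pure, total function over the region enum.
#'
#' @param region character vector of region codes.
#' @return character vector, `"proximal"` or `"distal"`.
#' @examples
#' regionSection(c("Py", "Ca"))
#' @export
regionSection <- function(region) {
  region <- as.character(region)
  .assertRegions(region)
  ifelse(region %in% PROXIMAL_REGIONS, "proximal", "distal")
}

#' Read a protein-by-sample abundance matrix from TSV
#'
#' Expects a tab-separated file whose header row carries the sample IDs and
#' whose first column (header `protein`) carries the gene symbols.  Values
#' must be nonnegative reals; 0 means "not detected".  Duplicate protein or
#' sample IDs and negative or non-numeric values are rejected.
#'
#' @param path TSV file path.
#' @param scale abundance scale tag of the stored values.
#' @return a [ProteomeMatrix-class].
#' @export
readAbundanceMatrix <- function(path, scale = c("ibaq", "fot", "ifot")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("malformed abundance TSV (need a protein column plus >= 1 sample): ", path)
  prot <- as.character(df[[1]])
  if (anyDuplicated(prot))
    stop("duplicate protein id(s) in ", path, ": ",
         paste(utils::head(unique(prot[duplicated(prot)]), 5), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  nonnum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonnum))
    stop("non-numeric abundance column(s): ",
         paste(colnames(vals)[nonnum], collapse = ", "))
  m <- as.matrix(vals)
  if (anyNA(m)) stop("missing values in ", path, " (use 0 for not detected)")
  if (any(m < 0)) stop("negative abundance values in ", path)
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample id(s) in ", path)
  rownames(m) <- prot
  ProteomeMatrix(m, scale = scale)
}

#' Write a ProteomeMatrix to TSV
#'
#' @param object a [ProteomeMatrix-class].
#' @param path output path; first column header is `protein`.
#' @return invisibly, `path`.
#' @export
writeAbundanceMatrix <- function(object, path) {
  m <- abundanceValues(object)
  df <- data.frame(protein = rownames(m),
                   apply(m, 2, fmtNum),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("protein", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Required columns: `sample`, `subject`, `region` (one of Ca, Fu, LC, GC,
#' AI, An, Py) and `tissue_class` (N, TNT or T).  Optional columns `lauren`
#' (diffuse/intestinal/mixed), `os_time` (months) and `os_event` (0/1) are
#' carried through.  The stomach `section` is derived from the region.
#'
#' @param path TSV file path.
#' @return a `data.frame` with a derived `section` column.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "subject", "region", "tissue_class")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample))
    stop("duplicate sample id(s) in metadata: ",
         paste(utils::head(unique(df$sample[duplicated(df$sample)]), 5),
               collapse = ", "))
  .assertRegions(df$region)
  badc <- setdiff(unique(df$tissue_class), .TISSUE_CLASSES)
  if (length(badc))
    stop("unknown tissue_class value(s): ", paste(badc, collapse = ", "))
  if ("lauren" %in% colnames(df)) {
    badl <- setdiff(stats::na.omit(unique(df$lauren)),
                    c("diffuse", "intestinal", "mixed", ""))
    if (length(badl))
      stop("unknown lauren value(s): ", paste(badl, collapse = ", "))
  }
  if ("os_time" %in% colnames(df) && any(df$os_time < 0, na.rm = TRUE))
    stop("os_time must be nonnegative")
  df$section <- regionSection(df$region)
  df
}

#' Read a per-sample per-protein peptide-evidence table from TSV
#'
#' Columns: `protein`, `sample`, `unique_peptides`, `strict_peptides`
#' (strict = peptides with search-engine ion score > 20, counted upstream).
#' A (protein, sample) pair may appear at most once; the two counts are
#' independent (neither bounds the other).
#'
#' @param path TSV file path.
#' @return a `data.frame`.
#' @export
readProteinEvidence <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "sample", "unique_peptides", "strict_peptides")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("evidence table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df[, c("protein", "sample")]))
    stop("duplicate (protein, sample) pair(s) in evidence table")
  for (cc in c("unique_peptides", "strict_peptides")) {
    v <- df[[cc]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != round(v)))
      stop(cc, " must be nonnegative integers")
    df[[cc]] <- as.integer(v)
  }
  df
}

#' @describeIn writeResults abundance matrix as protein x sample TSV.
#' @export
setMethod("writeResults", "ProteomeMatrix", function(object, path)
  writeAbundanceMatrix(object, path))

#' @describeIn writeResults one row per protein: `protein_id`, `n_ref`,
#'   `p10`, `p90`, `upper`, `defined`.
#' @export
setMethod("writeResults", "ReferenceIntervalSet", function(object, path) {
  ri <- as.data.frame(object@intervals)
  for (cc in c("p10", "p90", "upper")) ri[[cc]] <- fmtNum(ri[[cc]])
  utils::write.table(ri, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
})

#' Read back a reference-interval table written by [writeResults()]
#' @param path TSV file path.
#' @return a [ReferenceIntervalSet-class].
#' @export
readReferenceIntervals <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  new("ReferenceIntervalSet",
      intervals = S4Vectors::DataFrame(
        protein_id = as.character(df$protein_id),
        n_ref = as.integer(df$n_ref),
        p10 = as.numeric(df$p10), p90 = as.numeric(df$p90),
        upper = as.numeric(df$upper), defined = as.logical(df$defined)),
      params = list())
}

#' @describeIn writeResults samples x proteins 0/1 call matrix with a
#'   leading `sample` column and a trailing `n_outliers` count column.
#' @export
setMethod("writeResults", "OutlierCalls", function(object, path) {
  cl <- object@calls
  df <- data.frame(sample = rownames(cl),
                   matrix(as.integer(cl), nrow = nrow(cl),
                          dimnames = list(NULL, colnames(cl))),
                   n_outliers = object@counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
})

#' Read back an outlier-call table written by [writeResults()]
#' @param path TSV file path.
#' @return an [OutlierCalls-class].
#' @export
readOutlierCalls <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  prot <- setdiff(colnames(df), c("sample", "n_outliers"))
  cl <- as.matrix(df[, prot, drop = FALSE]) > 0
  rownames(cl) <- df$sample
  new("OutlierCalls", calls = cl,
      counts = stats::setNames(as.integer(df$n_outliers), df$sample))
}

#' @describeIn writeResults one row per item: `sample`, one `k<k>` column of
#'   labels per evaluated k, preceded by `#` header lines recording
#'   `chosen_k` and `seed`.  Consensus matrices are written alongside as
#'   `<path>.consensus_k<k>.tsv`.
#' @export
setMethod("writeResults", "SubtypeResult", function(object, path) {
  con <- file(path, "w")
  writeLines(sprintf("# chosen_k\t%d", object@chosenK), con)
  writeLines(sprintf("# seed\t%d", object@seed), con)
  am <- object@assignments
  df <- data.frame(sample = colnames(am),
                   t(am), check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample", paste0("k", rownames(am)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  for (k in as.character(object@kRange)) {
    cm <- object@consensus[[k]]
    cdf <- data.frame(sample = rownames(cm), apply(cm, 2, fmtNum),
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(cdf, sprintf("%s.consensus_k%s.tsv", path, k),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
})

#' Read back subtype assignments written by [writeResults()]
#' @param path TSV file path.
#' @return list with `assignments` (k x item integer matrix), `chosen_k`,
#'   `seed`.
#' @export
readSubtypeAssignments <- function(path) {
  hdr <- readLines(path, n = 2)
  chosen <- as.integer(sub("^# chosen_k\t", "", hdr[1]))
  seed <- as.integer(sub("^# seed\t", "", hdr[2]))
  df <- utils::read.delim(path, skip = 2, check.names = FALSE,
                          stringsAsFactors = FALSE)
  am <- t(as.matrix(df[, -1, drop = FALSE]))
  storage.mode(am) <- "integer"
  rownames(am) <- sub("^k", "", rownames(am))
  colnames(am) <- df$sample
  list(assignments = am, chosen_k = chosen, seed = seed)
}

#' @describeIn writeResults plain data.frame, full-precision numerics.
#' @export
setMethod("writeResults", "data.frame", function(object, path) {
  df <- object
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmtNum)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
})
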