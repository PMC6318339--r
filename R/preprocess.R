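#' Normalize iBAQ abundances to fraction of total (FOT)
#'
#' Divides each protein's iBAQ value by the summed iBAQ of all proteins in
#' that sample, so every column of an unfiltered matrix sums to 1.  Zeros
#' (not detected) stay zero.  FOT is computed on the full identification
#' matrix, before any row filtering: the denominator is the sum over all
#' proteins in the sample.
#'
#' @param matrix a [ProteomeMatrix-class] with scale `"ibaq"`.
#' @return a [ProteomeMatrix-class] with scale `"fot"`.
#' @examples
#' m <- matrix(c(2, 3, 5), dimnames = list(paste0("P", 1:3), "s1"))
#' abundanceValues(computeFOT(ProteomeMatrix(m, "ibaq")))
#' @export
computeFOT <- function(matrix) {
  stopifnot(is(matrix, "ProteomeMatrix"))
  if (abundanceScale(matrix) != "ibaq")
    stop("computeFOT expects an iBAQ-scale matrix, got ", abundanceScale(matrix))
  a <- abundanceValues(matrix)
  tot <- colSums(a)
  if (any(tot == 0))
    stop("sample(s) with no detected protein: ",
         paste(colnames(a)[tot == 0], collapse = ", "))
  .retag(matrix, sweep(a, 2, tot, `/`), "fot")
}

#' Scale FOT to iFOT
#'
#' Multiplies FOT values by 1e5 so that low-abundance proteins print on a
#' readable scale; columns of an unfiltered matrix sum to 1e5.
#'
#' @param matrix a [ProteomeMatrix-class] with scale `"fot"`.
#' @return a [ProteomeMatrix-class] with scale `"ifot"`.
#' @export
computeIFOT <- function(matrix) {
  stopifnot(is(matrix, "ProteomeMatrix"))
  if (abundanceScale(matrix) != "fot")
    stop("computeIFOT expects a FOT-scale matrix, got ", abundanceScale(matrix))
  .retag(matrix, abundanceValues(matrix) * 1e5, "ifot")
}

#' High-confidence peptide-evidence filter
#'
#' A (protein, sample) detection is retained iff it is backed by at least
#' one unique peptide and at least two strict peptides (peptides with
#' search-engine ion score > 20, counted upstream).
#'
#' @param evidence evidence data.frame from [readProteinEvidence()] or
#'   [simulateReferenceCohort()].
#' @param min_unique,min_strict thresholds (defaults 1 and 2).
#' @return named list: for each sample, the character vector of proteins
#'   whose detection passes the filter.
#' @export
filterEvidence <- function(evidence, min_unique = 1L, min_strict = 2L) {
  keep <- evidence$unique_peptides >= min_unique &
    evidence$strict_peptides >= min_strict
  ev <- evidence[keep, , drop = FALSE]
  split(ev$protein, factor(ev$sample, levels = unique(evidence$sample)))
}

#' Zero matrix entries lacking high-confidence evidence
#'
#' Applies [filterEvidence()] to a matrix: any detected entry whose
#' (protein, sample) pair is not in the evidence-passing set is set to 0.
#' Entries of samples absent from the evidence table are left untouched.
#'
#' @param matrix a [ProteomeMatrix-class].
#' @param detections output of [filterEvidence()].
#' @return a [ProteomeMatrix-class] of the same scale.
#' @export
maskByEvidence <- function(matrix, detections) {
  a <- abundanceValues(matrix)
  for (s in intersect(colnames(a), names(detections))) {
    drop <- a[, s] > 0 & !(rownames(a) %in% detections[[s]])
    a[drop, s] <- 0
  }
  .retag(matrix, a, abundanceScale(matrix))
}

#' Reproducibility filter: detected in two cases of one region
#'
#' A protein enters the high-confidence set iff at least one region has two
#' or more distinct samples detecting it.  With
#' `distinct_subjects = TRUE` the two cases must additionally come from
#' different subjects (in the reference design each subject contributes at
#' most one sample per region, so the distinction does not arise there).
#'
#' @param detections named list of per-sample detected protein sets
#'   (e.g. from [filterEvidence()], or computed from a matrix as
#'   `value > 0`).
#' @param metadata sample metadata with columns `sample`, `region` and
#'   (if `distinct_subjects`) `subject`.
#' @param min_cases minimum number of detecting cases in a single region
#'   (default 2).
#' @param distinct_subjects require the cases to be distinct subjects.
#' @return character vector: the global high-confidence protein set.
#' @export
filterReproducibility <- function(detections, metadata, min_cases = 2L,
                                  distinct_subjects = FALSE) {
  metadata <- as.data.frame(metadata)
  miss <- setdiff(names(detections), metadata$sample)
  if (length(miss))
    stop("samples missing from metadata: ", paste(miss, collapse = ", "))
  long <- data.frame(
    protein = unlist(detections, use.names = FALSE),
    sample = rep(names(detections), lengths(detections)),
    stringsAsFactors = FALSE)
  if (!nrow(long)) return(character())
  idx <- match(long$sample, metadata$sample)
  long$region <- metadata$region[idx]
  if (distinct_subjects) {
    long$case <- metadata$subject[idx]
    long <- unique(long[, c("protein", "region", "case")])
  } else {
    long <- unique(long[, c("protein", "region", "sample")])
  }
  cases <- stats::aggregate(list(n = seq_len(nrow(long))),
                            by = long[, c("protein", "region")], FUN = length)
  sort(unique(cases$protein[cases$n >= min_cases]))
}

#' Run the full preprocessing stage
#'
#' iBAQ -> FOT -> iFOT on the full identification matrix, then the
#' peptide-evidence mask, then the reproducibility row filter.  Column sums
#' of the returned filtered iFOT matrix may fall below 1e5 because
#' normalization precedes filtering (the FOT denominator is defined over all
#' identified proteins of a sample).
#'
#' @param matrix iBAQ-scale [ProteomeMatrix-class].
#' @param evidence evidence data.frame (or NULL to skip the evidence mask,
#'   e.g. for tumor cohorts quantified elsewhere).
#' @param metadata sample metadata.
#' @param min_unique,min_strict,min_cases,distinct_subjects filter settings,
#'   see [filterEvidence()] and [filterReproducibility()].
#' @return list: `ifot` (filtered iFOT matrix), `kept_proteins`, and a
#'   `report` data.frame of protein counts before/after filtering, per
#'   region.
#' @export
preprocessCohort <- function(matrix, evidence, metadata,
                             min_unique = 1L, min_strict = 2L,
                             min_cases = 2L, distinct_subjects = FALSE) {
  ifot <- computeIFOT(computeFOT(matrix))
  if (!is.null(evidence)) {
    det <- filterEvidence(evidence, min_unique, min_strict)
    ifot <- maskByEvidence(ifot, det)
  }
  a <- abundanceValues(ifot)
  det_sets <- apply(a > 0, 2, function(z) rownames(a)[z], simplify = FALSE)
  kept <- filterReproducibility(det_sets, metadata, min_cases,
                                distinct_subjects)
  md <- .alignMetadata(ifot, metadata)
  ids_before <- colSums(abundanceValues(matrix) > 0)
  ids_after <- colSums(a[kept, , drop = FALSE] > 0)
  report <- data.frame(
    region = md$region, sample = colnames(a),
    proteins_identified = as.integer(ids_before),
    proteins_high_confidence = as.integer(ids_after),
    stringsAsFactors = FALSE)
  list(ifot = ifot[kept, ], kept_proteins = kept, report = report)
}
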