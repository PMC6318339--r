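#' Build per-protein reference intervals from the normal cohort
#'
#' For each protein, takes the abundance values across the reference
#' (tissue_class = N) samples, computes the 10th and 90th percentiles by
#' linear interpolation between order statistics (the "type 7" convention,
#' [stats::quantile()] default) and sets the upper limit of the reference
#' interval to `p90 + 3 * (p90 - p10)`.  Zeros (not detected) are included
#' by default: the RI then describes the abundance distribution over all
#' reference samples, which keeps it sensitive to proteins that are
#' normally absent — the interesting case for tumor outliers.  With
#' `detected_only = TRUE` percentiles are computed over detected values
#' only.  Proteins with fewer than `min_ref` reference values are kept with
#' `defined = FALSE` and never used for calling.
#'
#' @param matrix an iFOT-scale [ProteomeMatrix-class] covering the normal
#'   cohort (query samples, if present, are ignored via `metadata`).
#' @param metadata sample metadata; reference samples are those with
#'   `tissue_class == "N"`.
#' @param min_ref minimum reference values per protein (default 10;
#'   percentiles of fewer points are unstable).
#' @param detected_only compute percentiles over detected values only.
#' @return a [ReferenceIntervalSet-class].
#' @examples
#' m <- matrix(1:100, nrow = 1,
#'             dimnames = list("P1", sprintf("s%02d", 1:100)))
#' md <- data.frame(sample = colnames(m), subject = colnames(m),
#'                  region = "Ca", tissue_class = "N")
#' ri <- buildReferenceIntervals(ProteomeMatrix(m, "ifot"), md)
#' riTable(ri)  # p10 = 10.9, p90 = 90.1, upper = 327.7
#' @export
buildReferenceIntervals <- function(matrix, metadata, min_ref = 10L,
                                    detected_only = FALSE) {
  md <- .alignMetadata(matrix, metadata)
  refcols <- md$tissue_class == "N"
  if (!any(refcols)) stop("reference cohort is empty (no tissue_class 'N' samples)")
  a <- abundanceValues(matrix)[, refcols, drop = FALSE]
  stats_list <- apply(a, 1, function(x) {
    if (detected_only) x <- x[x > 0]
    n <- length(x)
    if (n < min_ref) return(c(n, NA_real_, NA_real_))
    q <- stats::quantile(x, c(0.1, 0.9), type = 7, names = FALSE)
    c(n, q)
  })
  n_ref <- as.integer(stats_list[1, ])
  p10 <- unname(stats_list[2, ])
  p90 <- unname(stats_list[3, ])
  upper <- p90 + 3 * (p90 - p10)
  defined <- !is.na(p10)
  new("ReferenceIntervalSet",
      intervals = S4Vectors::DataFrame(
        protein_id = rownames(a), n_ref = n_ref,
        p10 = p10, p90 = p90, upper = upper, defined = defined),
      params = list(min_ref = as.integer(min_ref),
                    detected_only = detected_only,
                    n_reference_samples = sum(refcols)))
}

#' Call outlier proteins in query samples
#'
#' A protein is an outlier in a query sample iff its abundance is strictly
#' greater than the upper limit of its reference interval ("higher than"
#' the limit: a value exactly at the limit is not called).  Proteins
#' without a defined RI are never called.  Only proteins present in both
#' the query matrix and the RI set are evaluated.
#'
#' @param query an iFOT-scale [ProteomeMatrix-class] of query samples.
#' @param ri a [ReferenceIntervalSet-class].
#' @return an [OutlierCalls-class] (samples x proteins; per-sample counts).
#' @export
callOutliers <- function(query, ri) {
  tab <- riTable(ri)
  common <- intersect(rownames(query), tab$protein_id)
  if (!length(common))
    stop("query proteins do not intersect the reference intervals")
  a <- abundanceValues(query)[common, , drop = FALSE]
  idx <- match(common, tab$protein_id)
  upper <- tab$upper[idx]
  defined <- tab$defined[idx]
  calls <- t(a > upper & defined)
  calls[is.na(calls)] <- FALSE
  counts <- as.integer(rowSums(calls))
  names(counts) <- rownames(calls)
  new("OutlierCalls", calls = calls, counts = counts)
}

#' Stability of per-protein summaries under subsampling
#'
#' Resamples a given fraction of the samples (with replacement by default),
#' recomputes every protein's median abundance in each resample, and
#' summarizes, per fraction, the distribution of those medians and their
#' dispersion (per-protein IQR across resamples).  Deterministic under a
#' fixed seed.
#'
#' @param matrix a [ProteomeMatrix-class].
#' @param fractions fractions of samples to draw (default 0.1..0.8).
#' @param reps resamples per fraction (default 100).
#' @param seed RNG seed.
#' @param replace sample with replacement (default TRUE).
#' @return data.frame with one row per fraction: `fraction`, `n_samples`
#'   (resample size), `median_of_medians` (grand median of per-protein
#'   median abundance), `mean_iqr` and `median_iqr` (mean/median over
#'   proteins of the across-rep IQR of the protein's median).
#' @export
subsampleStability <- function(matrix, fractions = seq(0.1, 0.8, by = 0.1),
                               reps = 100L, seed = 1L, replace = TRUE) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must be in (0, 1]")
  a <- abundanceValues(matrix)
  n <- ncol(a)
  withSeed(seed, {
    out <- lapply(fractions, function(f) {
      m <- ceiling(f * n)
      if (m < 2) stop("fraction ", f, " yields fewer than 2 samples")
      meds <- vapply(seq_len(reps), function(r) {
        cols <- sample.int(n, m, replace = replace)
        apply(a[, cols, drop = FALSE], 1, stats::median)
      }, numeric(nrow(a)))
      iqr <- apply(meds, 1, stats::IQR, type = 7)
      data.frame(fraction = f, n_samples = m,
                 median_of_medians = stats::median(meds),
                 mean_iqr = mean(iqr), median_iqr = stats::median(iqr))
    })
    do.call(rbind, out)
  })
}
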