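#' Per-region detection frequency of every protein
#'
#' For each protein and region, the fraction of that region's samples in
#' which the protein is detected (abundance > 0).  Detection-based atlas
#' statistics ([coreProteome()], [callRegionSpecific()]) are computed from
#' this table, making them invariant to any monotone rescaling of the
#' abundances.
#'
#' @param matrix a [ProteomeMatrix-class].
#' @param metadata sample metadata (columns `sample`, `region`).
#' @return numeric matrix, proteins x regions, entries in [0, 1].
#' @export
detectionFrequency <- function(matrix, metadata) {
  md <- .alignMetadata(matrix, metadata)
  .assertRegions(md$region)
  a <- abundanceValues(matrix) > 0
  regions <- intersect(STOMACH_REGIONS, unique(md$region))
  freq <- vapply(regions, function(r) {
    cols <- md$region == r
    rowMeans(a[, cols, drop = FALSE])
  }, numeric(nrow(a)))
  freq <- matrix(freq, nrow = nrow(a),
                 dimnames = list(rownames(a), regions))
  freq
}

#' The mucosa core proteome
#'
#' Proteins seen in all seven regions (detection frequency above
#' `min_freq`, default 0, in every region).
#'
#' @param freq protein x region detection-frequency matrix from
#'   [detectionFrequency()].
#' @param min_freq detection-frequency threshold (exclusive).
#' @return character vector of core proteins.
#' @export
coreProteome <- function(freq, min_freq = 0) {
  if (ncol(freq) < length(STOMACH_REGIONS))
    stop("core proteome needs detection frequencies for all 7 regions")
  rownames(freq)[rowSums(freq > min_freq) == ncol(freq)]
}

#' Call region-specific (region-enriched) proteins
#'
#' A protein is region-enriched when it is reproducibly seen (detection
#' frequency >= `hi`, default 75%, boundary inclusive) in 1 or 2 regions
#' and rarely seen (frequency <= `lo`, default 25%) elsewhere.  Under the
#' default strict reading every non-enriched region must be rare; the loose
#' reading only requires at least 3 rare regions.  Frequencies that fall in
#' the gap between `lo` and `hi` outside an otherwise enriched pattern make
#' the protein `"other"`.
#'
#' @param freq protein x region detection-frequency matrix.
#' @param hi,lo frequency thresholds (inclusive).
#' @param rule `"strict"` (all other regions rare) or `"loose"` (>= 3
#'   regions rare).
#' @return data.frame with `protein_id`, `label` (`core` is not assigned
#'   here: `region_enriched` or `other`) and `enriched_regions`
#'   (comma-joined, empty unless enriched).
#' @export
callRegionSpecific <- function(freq, hi = 0.75, lo = 0.25,
                               rule = c("strict", "loose")) {
  rule <- match.arg(rule)
  E <- freq >= hi
  nE <- rowSums(E)
  rare <- freq <= lo
  ok_size <- nE >= 1 & nE <= 2
  ok_rest <- if (rule == "strict") {
    rowSums(rare | E) == ncol(freq)   # every non-enriched region rare
  } else {
    rowSums(rare & !E) >= 3
  }
  enriched <- ok_size & ok_rest
  regions <- colnames(freq)
  data.frame(
    protein_id = rownames(freq),
    label = ifelse(enriched, "region_enriched", "other"),
    enriched_regions = vapply(seq_len(nrow(freq)), function(i)
      if (enriched[i]) paste(regions[E[i, ]], collapse = ",") else "",
      character(1)),
    stringsAsFactors = FALSE)
}

#' Region correlation matrix and proximal/distal bipartition
#'
#' Represents each region by the mean per-sample FOT of every protein,
#' computes the Spearman correlation matrix between the seven region
#' vectors, and cuts an average-linkage hierarchical clustering of
#' 1 - correlation at two clusters.  On stomach mucosa data this recovers
#' the proximal {Ca, Fu, LC, GC} versus distal {AI, An, Py} sections.
#'
#' @param matrix an iFOT-scale [ProteomeMatrix-class].
#' @param metadata sample metadata.
#' @return list: `correlation` (region x region Spearman matrix),
#'   `sections` (named integer vector of cluster ids 1/2 per region) and
#'   `region_means` (protein x region mean-abundance matrix).
#' @export
regionCorrelationSections <- function(matrix, metadata) {
  md <- .alignMetadata(matrix, metadata)
  a <- abundanceValues(matrix)
  regions <- intersect(STOMACH_REGIONS, unique(md$region))
  if (any(table(factor(md$region, regions)) < 2))
    stop("every region needs >= 2 samples")
  rm_mat <- vapply(regions, function(r)
    rowMeans(a[, md$region == r, drop = FALSE]), numeric(nrow(a)))
  if (any(apply(rm_mat, 2, stats::sd) == 0))
    stop("constant region abundance vector; correlation undefined")
  cormat <- stats::cor(rm_mat, method = "spearman")
  hc <- stats::hclust(stats::as.dist(1 - cormat), method = "average")
  sections <- stats::cutree(hc, k = 2)
  list(correlation = cormat, sections = sections, region_means = rm_mat)
}

#' Section-marker proteins (proximal vs distal differential expression)
#'
#' Flags proteins with at least a fourfold expression difference
#' (`|log2FC| >= lfc`, computed on arithmetic mean iFOT with a pseudocount)
#' and Student's two-sample t-test p < `alpha` on log2(iFOT + pseudocount)
#' between the proximal and distal sections.  Proteins with zero variance
#' in both groups are excluded with a warning (the test is undefined).
#'
#' @param matrix an iFOT-scale [ProteomeMatrix-class].
#' @param metadata sample metadata (the `section` column, or derived from
#'   `region`).
#' @param lfc log2 fold-change threshold (default 2, i.e. fourfold).
#' @param alpha p-value threshold (default 0.05, unadjusted as in the
#'   original analysis).
#' @param pseudocount added before log transform and fold change
#'   (default 0.01 iFOT units).
#' @param var_equal Student's equal-variance t-test (default); set FALSE
#'   for Welch.
#' @param adjust optional multiple-testing adjustment method passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); default `"none"`.
#' @return data.frame: `protein_id`, `log2fc` (proximal over distal), `p`,
#'   `p_adj`, `direction` (`proximal`, `distal` or `ns`).
#' @export
sectionMarkers <- function(matrix, metadata, lfc = 2, alpha = 0.05,
                           pseudocount = 0.01, var_equal = TRUE,
                           adjust = "none") {
  md <- .alignMetadata(matrix, metadata)
  sec <- if ("section" %in% colnames(md)) md$section else regionSection(md$region)
  if (sum(sec == "proximal") < 2 || sum(sec == "distal") < 2)
    stop("both sections need >= 2 samples")
  a <- abundanceValues(matrix)
  lg <- log2(a + pseudocount)
  prox <- sec == "proximal"
  m_p <- rowMeans(a[, prox, drop = FALSE]) + pseudocount
  m_d <- rowMeans(a[, !prox, drop = FALSE]) + pseudocount
  log2fc <- log2(m_p / m_d)
  v_p <- apply(lg[, prox, drop = FALSE], 1, stats::var)
  v_d <- apply(lg[, !prox, drop = FALSE], 1, stats::var)
  degenerate <- v_p == 0 & v_d == 0
  if (any(degenerate))
    warning(sum(degenerate), " protein(s) with zero variance in both sections excluded")
  p <- rep(NA_real_, nrow(a))
  idx <- which(!degenerate)
  p[idx] <- vapply(idx, function(i)
    stats::t.test(lg[i, prox], lg[i, !prox], var.equal = var_equal)$p.value,
    numeric(1))
  p_adj <- stats::p.adjust(p, method = adjust)
  flagged <- !is.na(p_adj) & p_adj < alpha & abs(log2fc) >= lfc
  data.frame(
    protein_id = rownames(a),
    log2fc = log2fc, p = p, p_adj = p_adj,
    direction = ifelse(!flagged, "ns",
                       ifelse(log2fc > 0, "proximal", "distal")),
    row.names = NULL, stringsAsFactors = FALSE)[!degenerate, ]
}

#' Co-expression modules of high-abundance proteins
#'
#' Restricts to proteins with median iFOT > `min_median` (default 1) in at
#' least one region, represents each by its 7-region median profile, and
#' cuts an average-linkage hierarchical clustering of 1 - Pearson
#' correlation between profiles at `n_modules` modules (default 5).
#' Proteins whose region profile is constant have no defined correlation
#' and are dropped with a warning.
#'
#' @param matrix an iFOT-scale [ProteomeMatrix-class].
#' @param metadata sample metadata.
#' @param n_modules number of modules.
#' @param min_median eligibility threshold on the per-region median iFOT.
#' @return named integer vector: module id per eligible protein.
#' @export
coexpressionModules <- function(matrix, metadata, n_modules = 5L,
                                min_median = 1) {
  md <- .alignMetadata(matrix, metadata)
  a <- abundanceValues(matrix)
  regions <- intersect(STOMACH_REGIONS, unique(md$region))
  med <- vapply(regions, function(r)
    apply(a[, md$region == r, drop = FALSE], 1, stats::median),
    numeric(nrow(a)))
  eligible <- rowSums(med > min_median) >= 1
  prof <- med[eligible, , drop = FALSE]
  constant <- apply(prof, 1, stats::sd) == 0
  if (any(constant)) {
    warning(sum(constant), " constant-profile protein(s) dropped from module detection")
    prof <- prof[!constant, , drop = FALSE]
  }
  if (nrow(prof) < n_modules)
    stop("fewer eligible proteins (", nrow(prof), ") than modules (", n_modules, ")")
  d <- stats::as.dist(1 - stats::cor(t(prof)))
  stats::cutree(stats::hclust(d, method = "average"), k = n_modules)
}

#' Per-protein coefficient of variation
#'
#' CV% = 100 * sd / mean of a protein's abundance over the samples in which
#' it is detected; undefined (NA) below 2 detections.  Uses the sample
#' standard deviation.
#'
#' @param matrix a [ProteomeMatrix-class].
#' @return list: `cv` (named per-protein CV%, NA where undefined) and
#'   `mean_cv` (cohort mean over defined CVs).
#' @export
proteinCV <- function(matrix) {
  a <- abundanceValues(matrix)
  if (ncol(a) < 2) stop("CV needs >= 2 samples")
  cv <- apply(a, 1, function(x) {
    x <- x[x > 0]
    if (length(x) < 2) return(NA_real_)
    100 * stats::sd(x) / mean(x)
  })
  list(cv = cv, mean_cv = mean(cv, na.rm = TRUE))
}

#' Abundance summary of a gene signature across tissue classes
#'
#' Summarizes the iFOT values of a user-supplied gene list (e.g. stomach- or
#' intestine-enriched genes) per tissue class (N, TNT, T) and stomach
#' section: pooled median and quartiles across the listed proteins and the
#' samples of each stratum.
#'
#' @param matrix an iFOT-scale [ProteomeMatrix-class].
#' @param metadata sample metadata with `tissue_class` and `section` (or
#'   `region`).
#' @param gene_list character vector of protein ids; must intersect the
#'   matrix rows.
#' @return data.frame: `tissue_class`, `section`, `n_samples`, `n_values`,
#'   `q1`, `median`, `q3`.
#' @export
signatureSummary <- function(matrix, metadata, gene_list) {
  md <- .alignMetadata(matrix, metadata)
  sec <- if ("section" %in% colnames(md)) md$section else regionSection(md$region)
  genes <- intersect(gene_list, rownames(matrix))
  if (!length(genes))
    stop("gene_list has no overlap with the matrix proteins")
  a <- abundanceValues(matrix)[genes, , drop = FALSE]
  strata <- unique(data.frame(tissue_class = md$tissue_class, section = sec,
                              stringsAsFactors = FALSE))
  out <- lapply(seq_len(nrow(strata)), function(i) {
    cols <- md$tissue_class == strata$tissue_class[i] & sec == strata$section[i]
    v <- as.vector(a[, cols, drop = FALSE])
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7)
    data.frame(tissue_class = strata$tissue_class[i],
               section = strata$section[i],
               n_samples = sum(cols), n_values = length(v),
               q1 = q[[1]], median = q[[2]], q3 = q[[3]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
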