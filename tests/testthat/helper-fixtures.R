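# Shared fixtures and independent oracles, all built in code.

# a down-scaled cohort configuration for fast end-to-end tests
smallConfig <- function(seed = 1, ...) {
  args <- list(
    n_proteins = 400,
    samples_per_region = c(Ca = 4, Fu = 4, LC = 4, GC = 4,
                           AI = 4, An = 4, Py = 4),
    n_region_specific = 10,
    n_section_markers = 30,
    n_subtypes = 3,
    outliers_per_subtype = 10,
    n_tumor_patients = 18,
    seed = seed)
  do.call(cohortConfig, utils::modifyList(args, list(...)))
}

# a ProteomeMatrix with explicit values and per-sample regions
makePM <- function(values, regions, scale = "ifot",
                   tissue_class = "N") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  md <- data.frame(sample = colnames(values),
                   subject = colnames(values),
                   region = rep_len(regions, ncol(values)),
                   tissue_class = rep_len(tissue_class, ncol(values)),
                   stringsAsFactors = FALSE)
  md$section <- regionSection(md$region)
  list(pm = ProteomeMatrix(values, scale, metadata = md), metadata = md)
}

# --- independent oracles ----------------------------------------------------

# type-7 percentile by direct order-statistic interpolation
oraclePercentile <- function(x, p) {
  x <- sort(unname(x))
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# evidence rule + reproducibility rule by explicit loops
oracleHighConfidence <- function(evidence, metadata, min_unique = 1,
                                 min_strict = 2, min_cases = 2) {
  kept <- character()
  for (p in unique(evidence$protein)) {
    for (r in unique(metadata$region)) {
      n_cases <- 0
      for (s in metadata$sample[metadata$region == r]) {
        rows <- evidence$protein == p & evidence$sample == s
        if (any(rows) &&
            evidence$unique_peptides[rows] >= min_unique &&
            evidence$strict_peptides[rows] >= min_strict)
          n_cases <- n_cases + 1
      }
      if (n_cases >= min_cases) kept <- c(kept, p)
    }
  }
  sort(unique(kept))
}

# the >=75% / <=25% region-specific rule, evaluated literally per protein
oracleRegionSpecific <- function(freq_row, hi = 0.75, lo = 0.25,
                                 rule = "strict") {
  E <- which(freq_row >= hi)
  if (length(E) < 1 || length(E) > 2) return(character())
  others <- setdiff(seq_along(freq_row), E)
  ok <- if (rule == "strict") all(freq_row[others] <= lo)
        else sum(freq_row[others] <= lo) >= 3
  if (ok) names(freq_row)[E] else character()
}

# pooled-variance two-sample t-test p-value from the textbook formula
oracleStudentT <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}
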