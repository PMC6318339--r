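#' Configuration for the synthetic mucosa cohort generator
#'
#' Bundles every knob of the simulator with defaults emulating the study
#' conditions of a region-resolved stomach mucosa cohort: 82 normal biopsy
#' samples spread over the seven anatomical regions, a ~7 orders of magnitude
#' abundance dynamic range, abundance-dependent detection, planted
#' region-specific proteins, a planted proximal/distal section effect, and
#' paired tumor / tumor-nearby (TNT) cohorts carrying planted outlier-protein
#' subtypes.
#'
#' @param n_proteins number of simulated proteins.
#' @param samples_per_region named integer vector over the seven regions;
#'   defaults to the reference cohort sizes Ca 12, Fu 12, LC 11, GC 12,
#'   AI 15, An 10, Py 10 (82 samples).
#' @param log10_abundance_range range of base log10 abundances; the default
#'   spans 7 decades.
#' @param detection_slope,detection_midpoint logistic detection model:
#'   a protein of true log10 abundance `a` is detected in a sample with
#'   probability `plogis(detection_slope * (a - detection_midpoint))`.
#' @param sigma_log10 per-entry lognormal measurement noise (sd on the log10
#'   scale).  The default 0.35 puts per-protein CV% near the 95% regime
#'   typical of label-free biopsy cohorts.
#' @param n_region_specific number of planted region-specific proteins
#'   (detected with probability 0.95 in their 1-2 enriched regions, 0.05
#'   elsewhere).
#' @param n_section_markers number of planted section markers (half
#'   proximal, half distal), shifted by `section_effect_log2` (log2 units)
#'   in their home section.
#' @param section_effect_log2 log2 abundance shift of section markers in
#'   their home section (default 2, i.e. a fourfold section ratio).
#' @param section_program_sd_log2 sd (log2) of the graded section program: a
#'   per-protein proximal-vs-distal shift drawn from N(0, sd) and applied as
#'   half in each direction, emulating the broad, mostly sub-fourfold
#'   expression differences between gland programs of the two sections.
#'   Planted markers, region-specific proteins and signature candidates are
#'   excluded so their constructions stay exact.
#' @param n_subtypes number of planted tumor subtypes.
#' @param outliers_per_subtype planted outlier-signature proteins per
#'   subtype.  Signature candidates are proteins sitting just above the
#'   detection floor in normal mucosa (baseline detection probability drawn
#'   from `signature_detect_range`, so they enter the high-confidence
#'   universe but have low, often zero, reference percentiles — the
#'   normally-near-absent proteins that tumors ectopically overexpress);
#'   they are disjoint from section markers and region-specific proteins.
#' @param signature_detect_range baseline detection-probability band of the
#'   signature candidates (default `c(0.10, 0.25)`).
#' @param outlier_boost_log2 log2 boost of a tumor sample's own subtype
#'   signature (default 4, i.e. 16-fold).
#' @param tnt_attenuation fraction of the tumor boost expressed in the
#'   paired TNT sample (default 0.5).
#' @param n_tumor_patients number of tumor/TNT pairs (default 58).
#' @param evidence_pass_prob probability that a detected entry receives
#'   filter-passing peptide evidence (>= 1 unique and >= 2 strict peptides).
#' @param seed integer RNG seed; identical seeds give bit-identical cohorts
#'   (R's default Mersenne-Twister generator).
#'
#' @return a validated list of class `CohortConfig`.
#' @examples
#' cfg <- cohortConfig(n_proteins = 500, seed = 7)
#' ref <- simulateReferenceCohort(cfg)
#' ref$matrix
#' @export
cohortConfig <- function(n_proteins = 2500,
                         samples_per_region = c(Ca = 12, Fu = 12, LC = 11,
                                                GC = 12, AI = 15, An = 10,
                                                Py = 10),
                         log10_abundance_range = c(-1.5, 5.5),
                         detection_slope = 8,
                         detection_midpoint = 1.5,
                         sigma_log10 = 0.35,
                         n_region_specific = 70,
                         n_section_markers = 140,
                         section_effect_log2 = 2,
                         section_program_sd_log2 = 0.75,
                         n_subtypes = 3,
                         outliers_per_subtype = 40,
                         outlier_boost_log2 = 4,
                         signature_detect_range = c(0.10, 0.25),
                         tnt_attenuation = 0.5,
                         n_tumor_patients = 58,
                         evidence_pass_prob = 0.95,
                         seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              samples_per_region = unlist(samples_per_region),
              log10_abundance_range = as.numeric(log10_abundance_range),
              detection_slope = detection_slope,
              detection_midpoint = detection_midpoint,
              sigma_log10 = sigma_log10,
              n_region_specific = as.integer(n_region_specific),
              n_section_markers = as.integer(n_section_markers),
              section_effect_log2 = section_effect_log2,
              section_program_sd_log2 = section_program_sd_log2,
              n_subtypes = as.integer(n_subtypes),
              outliers_per_subtype = as.integer(outliers_per_subtype),
              outlier_boost_log2 = outlier_boost_log2,
              signature_detect_range = as.numeric(signature_detect_range),
              tnt_attenuation = tnt_attenuation,
              n_tumor_patients = as.integer(n_tumor_patients),
              evidence_pass_prob = evidence_pass_prob,
              seed = as.integer(seed))
  if (cfg$n_proteins < 1) stop("n_proteins must be positive")
  if (!setequal(names(cfg$samples_per_region), STOMACH_REGIONS))
    stop("samples_per_region must name all seven regions (",
         paste(STOMACH_REGIONS, collapse = ", "), ")")
  cfg$samples_per_region <- cfg$samples_per_region[STOMACH_REGIONS]
  if (any(cfg$samples_per_region < 1)) stop("every region needs >= 1 sample")
  if (diff(cfg$log10_abundance_range) <= 0)
    stop("log10_abundance_range must be increasing")
  p <- stats::plogis(cfg$detection_slope *
                       (cfg$log10_abundance_range - cfg$detection_midpoint))
  if (any(!is.finite(p)) || cfg$detection_slope <= 0)
    stop("detection model must give probabilities in (0,1) over the range")
  if (cfg$sigma_log10 < 0) stop("sigma_log10 must be nonnegative")
  if (cfg$section_program_sd_log2 < 0)
    stop("section_program_sd_log2 must be nonnegative")
  if (cfg$tnt_attenuation < 0 || cfg$tnt_attenuation > 1)
    stop("tnt_attenuation must be in [0, 1]")
  if (any(cfg$signature_detect_range <= 0) ||
      any(cfg$signature_detect_range >= 1) ||
      diff(cfg$signature_detect_range) <= 0)
    stop("signature_detect_range must be an increasing pair inside (0, 1)")
  if (cfg$n_subtypes * cfg$outliers_per_subtype > cfg$n_proteins)
    stop("outliers_per_subtype * n_subtypes exceeds n_proteins")
  if (cfg$n_region_specific + cfg$n_section_markers +
      cfg$n_subtypes * cfg$outliers_per_subtype >= cfg$n_proteins)
    stop("too many planted proteins for n_proteins")
  class(cfg) <- "CohortConfig"
  cfg
}

# baseline per-protein detection probability under the logistic model
.baseDetectProb <- function(cfg, log10_abundance) {
  stats::plogis(cfg$detection_slope * (log10_abundance - cfg$detection_midpoint))
}

# Simulate abundance values for samples with the given regions.
# extra_log2: optional protein x sample matrix of additional log2 shifts
# (tumor / TNT signature boosts).  Uses the ambient RNG stream.
.simulateValues <- function(cfg, truth, sample_regions, sample_ids,
                            extra_log2 = NULL) {
  n <- cfg$n_proteins
  m <- length(sample_regions)
  true_log10 <- matrix(truth$base_log10, nrow = n, ncol = m,
                       dimnames = list(truth$protein_ids, sample_ids))
  sec <- regionSection(sample_regions)
  for (side in c("proximal", "distal")) {
    mk <- names(truth$section_markers)[truth$section_markers == side]
    home <- sec == side
    if (length(mk) && any(home))
      true_log10[mk, home] <- true_log10[mk, home] +
        cfg$section_effect_log2 * log10(2)
  }
  prog <- truth$section_program_log2
  if (!is.null(prog) && any(prog != 0)) {
    half <- prog * log10(2) / 2
    prox <- sec == "proximal"
    true_log10[, prox] <- true_log10[, prox] + half
    true_log10[, !prox] <- true_log10[, !prox] - half
  }
  if (!is.null(extra_log2)) true_log10 <- true_log10 + extra_log2 * log10(2)

  pdet <- .baseDetectProb(cfg, true_log10)
  rs <- truth$region_specific_proteins
  if (length(rs)) {
    enriched <- vapply(seq_len(m), function(j)
      vapply(rs, function(set) sample_regions[j] %in% set, logical(1)),
      logical(length(rs)))
    enriched <- matrix(enriched, nrow = length(rs))
    pdet[names(rs), ] <- ifelse(enriched, 0.95, 0.05)
  }

  detected <- matrix(stats::runif(n * m) < pdet, nrow = n)
  measured <- 10^(true_log10 + matrix(stats::rnorm(n * m, sd = cfg$sigma_log10),
                                      nrow = n))
  vals <- ifelse(detected, measured, 0)
  dimnames(vals) <- list(truth$protein_ids, sample_ids)
  vals
}

#' Simulate the normal (reference) mucosa cohort
#'
#' Draws per-protein base log10 abundances uniformly over the configured
#' dynamic range, plants region-specific proteins and proximal/distal
#' section markers, applies lognormal measurement noise, thins entries by
#' the logistic detection model (undetected entries are 0) and emits a
#' matching peptide-evidence table.  Identical seeds give bit-identical
#' output.
#'
#' @param config a [cohortConfig()].
#' @return list with elements `matrix` (a [ProteomeMatrix-class], scale
#'   `"ibaq"`), `metadata` (data.frame), `evidence` (data.frame) and `truth`
#'   (class `SyntheticTruth`: planted structure and generator state needed
#'   to simulate matched query cohorts).
#' @export
simulateReferenceCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  withSeed(config$seed, {
    n <- config$n_proteins
    prot <- sprintf("P%05d", seq_len(n))
    base_log10 <- stats::runif(n, config$log10_abundance_range[1],
                               config$log10_abundance_range[2])
    names(base_log10) <- prot

    rs_idx <- sample(n, config$n_region_specific)
    region_specific <- lapply(rs_idx, function(i) {
      r <- sample(STOMACH_REGIONS, 1)
      if (stats::runif(1) < 0.2) {
        side <- if (r %in% PROXIMAL_REGIONS) PROXIMAL_REGIONS else DISTAL_REGIONS
        unique(c(r, sample(setdiff(side, r), 1)))
      } else r
    })
    names(region_specific) <- prot[rs_idx]

    mk_idx <- sample(setdiff(seq_len(n), rs_idx), config$n_section_markers)
    section_markers <- rep(c("proximal", "distal"),
                           length.out = config$n_section_markers)
    names(section_markers) <- prot[mk_idx]

    # Outlier-signature candidates: proteins just above the detection floor
    # of normal mucosa.  Their base abundance is redrawn so their baseline
    # detection probability lies in signature_detect_range: rare enough for
    # low (often zero) reference percentiles, frequent enough to survive the
    # two-cases-in-one-region reproducibility filter.
    n_sig <- config$n_subtypes * config$outliers_per_subtype
    sig_idx <- sample(setdiff(seq_len(n), c(rs_idx, mk_idx)), n_sig)
    plo <- stats::qlogis(config$signature_detect_range)
    base_log10[sig_idx] <- config$detection_midpoint +
      stats::runif(n_sig, plo[1], plo[2]) / config$detection_slope

    program <- numeric(n)
    free_idx <- setdiff(seq_len(n), c(rs_idx, mk_idx, sig_idx))
    program[free_idx] <- stats::rnorm(length(free_idx),
                                      sd = config$section_program_sd_log2)
    names(program) <- prot

    truth <- structure(list(
      protein_ids = prot,
      base_log10 = base_log10,
      region_specific_proteins = region_specific,
      section_markers = section_markers,
      section_program_log2 = program,
      signature_candidates = prot[sig_idx],
      subtype_labels = NULL,
      outlier_signature = NULL,
      config = config), class = "SyntheticTruth")

    nper <- config$samples_per_region
    regions <- rep(names(nper), nper)
    ids <- unlist(lapply(names(nper), function(r)
      sprintf("N_%s_%02d", r, seq_len(nper[[r]]))), use.names = FALSE)
    metadata <- data.frame(
      sample = ids,
      subject = unlist(lapply(nper, function(k) sprintf("SUBJ%02d", seq_len(k))),
                       use.names = FALSE),
      region = regions,
      tissue_class = "N",
      stringsAsFactors = FALSE)
    metadata$section <- regionSection(metadata$region)

    vals <- .simulateValues(config, truth, regions, ids)

    det <- which(vals > 0, arr.ind = TRUE)
    nd <- nrow(det)
    pass <- stats::runif(nd) < config$evidence_pass_prob
    uniq <- integer(nd); strict <- integer(nd)
    uniq[pass] <- 1L + stats::rpois(sum(pass), 2)
    strict[pass] <- 2L + stats::rpois(sum(pass), 3)
    fail_no_unique <- !pass & stats::runif(nd) < 0.5
    uniq[fail_no_unique] <- 0L
    strict[fail_no_unique] <- stats::rpois(sum(fail_no_unique), 3)
    fail_few_strict <- !pass & !fail_no_unique
    uniq[fail_few_strict] <- 1L + stats::rpois(sum(fail_few_strict), 1)
    strict[fail_few_strict] <- sample(0:1, sum(fail_few_strict), replace = TRUE)
    evidence <- data.frame(protein = rownames(vals)[det[, 1]],
                           sample = colnames(vals)[det[, 2]],
                           unique_peptides = uniq,
                           strict_peptides = strict,
                           stringsAsFactors = FALSE)

    list(matrix = ProteomeMatrix(vals, "ibaq", metadata = metadata),
         metadata = metadata, evidence = evidence, truth = truth)
  })
}

#' Simulate paired tumor and tumor-nearby cohorts with planted subtypes
#'
#' For `n_tumor_patients` subjects, simulates a tumor (T) and a paired
#' tumor-nearby-tissue (TNT) sample from the same stomach region.  Each
#' patient belongs to one of `n_subtypes` planted subtypes; the tumor sample
#' boosts its subtype's outlier-signature proteins by `outlier_boost_log2`
#' (log2) and the TNT sample expresses the same boost scaled by
#' `tnt_attenuation`.  Signature proteins are drawn from proteins that are
#' normally almost absent, so per-sample expected outlier counts are ordered
#' T > TNT > normal by construction.  Non-signature proteins follow the
#' reference model.
#'
#' @param config a [cohortConfig()] (the one used for the reference cohort).
#' @param reference_truth the `truth` element returned by
#'   [simulateReferenceCohort()].
#' @return list with `tumor` and `tnt` ([ProteomeMatrix-class], scale
#'   `"ibaq"`), `metadata` (rows for both T and TNT samples, with `lauren`,
#'   `os_time`, `os_event`) and an extended `truth` carrying
#'   `subtype_labels` (tumor sample -> integer) and `outlier_signature`
#'   (subtype -> protein set).
#' @export
simulateTumorCohort <- function(config, reference_truth) {
  stopifnot(inherits(config, "CohortConfig"),
            inherits(reference_truth, "SyntheticTruth"))
  if (config$n_subtypes < 2) stop("n_subtypes must be >= 2")
  withSeed(stageSeed(config$seed, "tumor_cohort"), {
    truth <- reference_truth
    n_sig <- config$n_subtypes * config$outliers_per_subtype
    pool <- truth$signature_candidates
    if (length(pool) < n_sig)
      stop("reference truth provides ", length(pool),
           " signature candidates but ", n_sig, " are required; ",
           "regenerate the reference cohort with a matching config")
    sig <- sample(pool, n_sig)
    outlier_signature <- split(sig, rep(seq_len(config$n_subtypes),
                                        each = config$outliers_per_subtype))

    np <- config$n_tumor_patients
    subtype <- sample(rep_len(seq_len(config$n_subtypes), np))
    region <- sample(STOMACH_REGIONS, np, replace = TRUE)
    t_ids <- sprintf("T_%02d", seq_len(np))
    p_ids <- sprintf("TNT_%02d", seq_len(np))
    subj <- sprintf("GCA%02d", seq_len(np))

    boost <- matrix(0, config$n_proteins, np,
                    dimnames = list(truth$protein_ids, NULL))
    for (s in seq_len(config$n_subtypes))
      boost[outlier_signature[[s]], subtype == s] <- config$outlier_boost_log2

    tumor_vals <- .simulateValues(config, truth, region, t_ids, boost)
    tnt_vals <- .simulateValues(config, truth, region, p_ids,
                                boost * config$tnt_attenuation)

    lauren <- sample(c("diffuse", "intestinal", "mixed"), np,
                     replace = TRUE, prob = c(0.45, 0.4, 0.15))
    os_time <- round(stats::rexp(np, rate = 1 / 30), 1)
    os_event <- stats::rbinom(np, 1, 0.6)
    metadata <- data.frame(
      sample = c(t_ids, p_ids),
      subject = rep(subj, 2),
      region = rep(region, 2),
      tissue_class = rep(c("T", "TNT"), each = np),
      lauren = rep(lauren, 2),
      os_time = rep(os_time, 2),
      os_event = rep(os_event, 2),
      stringsAsFactors = FALSE)
    metadata$section <- regionSection(metadata$region)

    truth$subtype_labels <- stats::setNames(subtype, t_ids)
    truth$outlier_signature <- outlier_signature

    list(tumor = ProteomeMatrix(tumor_vals, "ibaq",
                                metadata = metadata[metadata$tissue_class == "T", ]),
         tnt = ProteomeMatrix(tnt_vals, "ibaq",
                              metadata = metadata[metadata$tissue_class == "TNT", ]),
         metadata = metadata, truth = truth)
  })
}

#' Simulate held-out normal query samples
#'
#' Draws additional normal samples from the same generative model (same
#' per-protein base abundances and planted structure) as the reference
#' cohort, for specificity checks of outlier calling on samples not used to
#' build the reference intervals.
#'
#' @param config a [cohortConfig()].
#' @param reference_truth the `truth` from [simulateReferenceCohort()].
#' @param n_samples number of held-out normal samples.
#' @return list with `matrix` ([ProteomeMatrix-class]) and `metadata`.
#' @export
simulateNormalQuery <- function(config, reference_truth, n_samples = 21) {
  stopifnot(inherits(config, "CohortConfig"),
            inherits(reference_truth, "SyntheticTruth"))
  withSeed(stageSeed(config$seed, "normal_query"), {
    region <- rep_len(STOMACH_REGIONS, n_samples)
    ids <- sprintf("Q_%s_%02d", region, seq_len(n_samples))
    metadata <- data.frame(sample = ids,
                           subject = sprintf("QSUBJ%02d", seq_len(n_samples)),
                           region = region, tissue_class = "N",
                           stringsAsFactors = FALSE)
    metadata$section <- regionSection(metadata$region)
    vals <- .simulateValues(config, reference_truth, region, ids)
    list(matrix = ProteomeMatrix(vals, "ibaq", metadata = metadata),
         metadata = metadata)
  })
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf("SyntheticTruth: %d proteins\n", length(x$protein_ids)))
  cat(sprintf("  region-specific: %d; section markers: %d\n",
              length(x$region_specific_proteins), length(x$section_markers)))
  if (!is.null(x$subtype_labels))
    cat(sprintf("  tumor subtypes: %d over %d patients (%d signature proteins each)\n",
                length(x$outlier_signature), length(x$subtype_labels),
                length(x$outlier_signature[[1]])))
  invisible(x)
}
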