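#' Run the full mucosa-atlas pipeline
#'
#' Orchestrates simulate (optional) -> preprocess -> atlas -> reference ->
#' outliers -> subtype with a single configuration and a single seed.  The
#' seed fans out to per-stage derived seeds (hashed from the stage name) so
#' stages can be rerun independently and reproducibly; rerunning the whole
#' pipeline with the same configuration and seed is bit-identical for
#' integer and boolean outputs.  Every stage failure aborts with the
#' failing stage named.  All artifacts are TSV files under `outdir`, plus a
#' timestamped log with the resolved configuration echoed.
#'
#' @param config configuration: a YAML file path or a nested list.  Keys
#'   (all optional): `seed`; `simulate` (arguments of [cohortConfig()]);
#'   `inputs` (instead of `simulate`: paths `matrix`, `metadata` and
#'   optionally `evidence`, `tumor_matrix`, `tnt_matrix`,
#'   `tumor_metadata`); `preprocess` (`min_unique`, `min_strict`,
#'   `min_cases`, `distinct_subjects`); `atlas` (`lfc`, `alpha`,
#'   `pseudocount`, `n_modules`, `region_rule`); `reference` (`min_ref`,
#'   `detected_only`); `subtype` (`k_min`, `k_max`, `reps`, `item_frac`,
#'   `forced_k`); `query_normals` (held-out normal sample count in
#'   simulate mode).
#' @param outdir artifact directory (created if needed); overrides
#'   `config$outdir`.
#' @param seed integer; overrides `config$seed`.
#' @return invisibly, a list with the main stage objects (`ifot`,
#'   `reference_intervals`, per-cohort `outliers`, `subtypes`, ...) and
#'   `artifacts` (named file paths).
#' @export
runPipeline <- function(config = list(), outdir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (is.null(seed)) seed <- if (!is.null(config$seed)) config$seed else 1L
  seed <- as.integer(seed)
  if (is.null(outdir)) outdir <- config$outdir
  if (is.null(outdir)) stop("an output directory is required (outdir)")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  logfile <- file.path(outdir, "pipeline.log")
  cat(sprintf("[%s] pipeline start (seed %d)\n",
              format(Sys.time(), "%Y-%m-%d %H:%M:%S"), seed),
      file = logfile)
  logmsg <- function(...) cat(sprintf("[%s] %s\n",
                                      format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                                      sprintf(...)),
                              file = logfile, append = TRUE)
  resolved <- utils::modifyList(
    list(seed = seed, outdir = outdir, query_normals = 21L,
         preprocess = list(), atlas = list(), reference = list(),
         subtype = list()),
    config)
  resolved$seed <- seed; resolved$outdir <- outdir
  writeLines(yaml::as.yaml(resolved), file.path(outdir, "config_resolved.yaml"))
  cat(yaml::as.yaml(resolved), file = logfile, append = TRUE)

  runStage <- function(name, expr) {
    logmsg("stage '%s' start", name)
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    logmsg("stage '%s' done", name)
    out
  }
  artifacts <- list()
  keep <- function(name, path) { artifacts[[name]] <<- path; path }

  ## --- simulate or load inputs --------------------------------------------
  tumor <- tnt <- tumor_md <- nquery <- NULL
  if (is.null(config$inputs)) {
    sim <- runStage("simulate", {
      args <- if (is.null(config$simulate)) list() else config$simulate
      args$seed <- stageSeed(seed, "simulate")
      cfg <- do.call(cohortConfig, args)
      ref <- simulateReferenceCohort(cfg)
      tum <- simulateTumorCohort(cfg, ref$truth)
      nq <- simulateNormalQuery(cfg, ref$truth,
                                n_samples = resolved$query_normals)
      writeAbundanceMatrix(ref$matrix, keep("matrix", file.path(outdir, "reference_ibaq.tsv")))
      writeResults(ref$metadata, keep("metadata", file.path(outdir, "reference_metadata.tsv")))
      writeResults(ref$evidence, keep("evidence", file.path(outdir, "reference_evidence.tsv")))
      writeAbundanceMatrix(tum$tumor, keep("tumor_matrix", file.path(outdir, "tumor_ibaq.tsv")))
      writeAbundanceMatrix(tum$tnt, keep("tnt_matrix", file.path(outdir, "tnt_ibaq.tsv")))
      writeResults(tum$metadata, keep("tumor_metadata", file.path(outdir, "tumor_metadata.tsv")))
      truth_df <- data.frame(
        item = c(names(tum$truth$section_markers),
                 names(tum$truth$region_specific_proteins),
                 names(tum$truth$subtype_labels),
                 unlist(tum$truth$outlier_signature, use.names = FALSE)),
        role = c(rep("section_marker", length(tum$truth$section_markers)),
                 rep("region_specific", length(tum$truth$region_specific_proteins)),
                 rep("subtype_label", length(tum$truth$subtype_labels)),
                 rep("outlier_signature",
                     length(unlist(tum$truth$outlier_signature)))),
        value = c(unname(tum$truth$section_markers),
                  vapply(tum$truth$region_specific_proteins,
                         paste, character(1), collapse = ","),
                  as.character(unname(tum$truth$subtype_labels)),
                  rep(names(tum$truth$outlier_signature),
                      lengths(tum$truth$outlier_signature))),
        stringsAsFactors = FALSE)
      writeResults(truth_df, keep("truth", file.path(outdir, "truth.tsv")))
      list(ref = ref, tum = tum, nq = nq)
    })
    mat <- sim$ref$matrix; evidence <- sim$ref$evidence
    metadata <- sim$ref$metadata
    tumor <- sim$tum$tumor; tnt <- sim$tum$tnt; tumor_md <- sim$tum$metadata
    nquery <- sim$nq
  } else {
    loaded <- runStage("inputs", {
      inp <- config$inputs
      if (is.null(inp$matrix)) stop("config$inputs$matrix path is missing")
      if (is.null(inp$metadata)) stop("config$inputs$metadata path is missing")
      out <- list(mat = readAbundanceMatrix(inp$matrix, scale = "ibaq"),
                  metadata = readSampleMetadata(inp$metadata),
                  evidence = if (!is.null(inp$evidence))
                    readProteinEvidence(inp$evidence))
      if (!is.null(inp$tumor_matrix))
        out$tumor <- readAbundanceMatrix(inp$tumor_matrix, scale = "ibaq")
      if (!is.null(inp$tnt_matrix))
        out$tnt <- readAbundanceMatrix(inp$tnt_matrix, scale = "ibaq")
      if (!is.null(inp$tumor_metadata))
        out$tumor_md <- readSampleMetadata(inp$tumor_metadata)
      out
    })
    mat <- loaded$mat; evidence <- loaded$evidence; metadata <- loaded$metadata
    tumor <- loaded$tumor; tnt <- loaded$tnt; tumor_md <- loaded$tumor_md
  }

  ## --- preprocess ----------------------------------------------------------
  pp <- runStage("preprocess", {
    args <- resolved$preprocess
    pp <- preprocessCohort(mat, evidence, metadata,
                           min_unique = args$min_unique %||% 1L,
                           min_strict = args$min_strict %||% 2L,
                           min_cases = args$min_cases %||% 2L,
                           distinct_subjects = isTRUE(args$distinct_subjects))
    writeAbundanceMatrix(pp$ifot, keep("ifot", file.path(outdir, "reference_ifot_filtered.tsv")))
    writeResults(pp$report, keep("filter_report", file.path(outdir, "filter_report.tsv")))
    pp
  })

  ## --- atlas ---------------------------------------------------------------
  atlas <- runStage("atlas", {
    args <- resolved$atlas
    freq <- detectionFrequency(pp$ifot, metadata)
    core <- coreProteome(freq)
    spec <- callRegionSpecific(freq, rule = args$region_rule %||% "strict")
    spec$label[spec$protein_id %in% core] <- "core"
    secs <- regionCorrelationSections(pp$ifot, metadata)
    markers <- sectionMarkers(pp$ifot, metadata,
                              lfc = args$lfc %||% 2,
                              alpha = args$alpha %||% 0.05,
                              pseudocount = args$pseudocount %||% 0.01)
    modules <- coexpressionModules(pp$ifot, metadata,
                                   n_modules = args$n_modules %||% 5L)
    cv <- proteinCV(pp$ifot)
    writeResults(data.frame(protein_id = rownames(freq), freq,
                            stringsAsFactors = FALSE),
                 keep("region_freq", file.path(outdir, "region_frequency.tsv")))
    writeResults(spec, keep("labels", file.path(outdir, "protein_labels.tsv")))
    writeResults(markers, keep("section_markers", file.path(outdir, "section_markers.tsv")))
    writeResults(data.frame(protein_id = names(modules),
                            module = as.integer(modules),
                            stringsAsFactors = FALSE),
                 keep("modules", file.path(outdir, "coexpression_modules.tsv")))
    writeResults(data.frame(protein_id = names(cv$cv), cv_pct = cv$cv,
                            stringsAsFactors = FALSE),
                 keep("cv", file.path(outdir, "protein_cv.tsv")))
    writeResults(data.frame(region = rownames(secs$correlation),
                            secs$correlation, stringsAsFactors = FALSE),
                 keep("correlation", file.path(outdir, "region_correlation.tsv")))
    list(freq = freq, core = core, labels = spec, sections = secs,
         markers = markers, modules = modules, cv = cv)
  })

  ## --- reference intervals -------------------------------------------------
  ri <- runStage("reference", {
    args <- resolved$reference
    ri <- buildReferenceIntervals(pp$ifot, metadata,
                                  min_ref = args$min_ref %||% 10L,
                                  detected_only = isTRUE(args$detected_only))
    writeResults(ri, keep("reference_intervals", file.path(outdir, "reference_intervals.tsv")))
    ri
  })

  ## --- outlier calling -----------------------------------------------------
  queryIFOT <- function(q) {
    ii <- computeIFOT(computeFOT(q))
    ii[intersect(rownames(ii), pp$kept_proteins), ]
  }
  cohorts <- list()
  if (!is.null(tumor)) cohorts$tumor <- queryIFOT(tumor)
  if (!is.null(tnt)) cohorts$tnt <- queryIFOT(tnt)
  if (!is.null(nquery)) cohorts$normal_heldout <- queryIFOT(nquery$matrix)
  outliers <- runStage("outliers", {
    lapply(stats::setNames(names(cohorts), names(cohorts)), function(nm) {
      calls <- callOutliers(cohorts[[nm]], ri)
      writeResults(calls, keep(paste0("calls_", nm),
                               file.path(outdir, sprintf("outlier_calls_%s.tsv", nm))))
      writeResults(data.frame(sample = names(outlierCounts(calls)),
                              n_outliers = as.integer(outlierCounts(calls)),
                              stringsAsFactors = FALSE),
                   keep(paste0("counts_", nm),
                        file.path(outdir, sprintf("outlier_counts_%s.tsv", nm))))
      calls
    })
  })

  ## --- subtyping -----------------------------------------------------------
  subtypes <- NULL
  if (!is.null(outliers$tumor)) {
    subtypes <- runStage("subtype", {
      args <- resolved$subtype
      q <- cohorts$tumor
      feats <- selectOutlierFeatures(outliers$tumor,
                                     t(abundanceValues(q) > 0),
                                     min_detect_frac = args$min_detect_frac %||% 0.20,
                                     min_outlier_frac = args$min_outlier_frac %||% 0.75)
      if (length(feats) < 3)
        stop("only ", length(feats), " outlier features selected; cannot subtype")
      x <- log2(abundanceValues(q)[feats, , drop = FALSE] + 0.01)
      res <- consensusCluster(x,
                              k_range = (args$k_min %||% 2L):(args$k_max %||% 10L),
                              reps = args$reps %||% 500L,
                              item_frac = args$item_frac %||% 0.9,
                              seed = stageSeed(seed, "subtype"))
      if (!is.null(args$forced_k)) res@chosenK <- as.integer(args$forced_k)
      writeResults(res, keep("subtypes", file.path(outdir, "subtype_assignments.tsv")))
      rep_md <- if (!is.null(tumor_md)) tumor_md else metadata
      rep_out <- subtypeReport(res, outliers$tumor, rep_md)
      writeResults(data.frame(protein_id = rownames(rep_out$outlier_freq),
                              rep_out$outlier_freq, stringsAsFactors = FALSE),
                   keep("subtype_outlier_freq",
                        file.path(outdir, "subtype_outlier_frequency.tsv")))
      writeResults(rep_out$members, keep("subtype_members",
                                         file.path(outdir, "subtype_members.tsv")))
      list(result = res, features = feats, report = rep_out)
    })
  }

  logmsg("pipeline done")
  invisible(list(ifot = pp$ifot, kept_proteins = pp$kept_proteins,
                 atlas = atlas, reference_intervals = ri,
                 outliers = outliers, subtypes = subtypes,
                 artifacts = artifacts, config = resolved))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
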