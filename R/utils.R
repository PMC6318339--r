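# Internal helpers shared across stages.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

# Derive a per-stage seed from a base seed so pipeline stages can be rerun
# independently yet reproducibly.  Kept well inside 32-bit integer range.
stageSeed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(seed) * 1009 + h) %% 2147483647)
}

# numeric formatting that survives TSV round-trips (17 significant digits
# round-trips IEEE doubles exactly)
fmtNum <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  gsub(" ", "", out)
}

.assertRegions <- function(region) {
  bad <- setdiff(unique(as.character(region)), STOMACH_REGIONS)
  if (length(bad))
    stop("unknown region code(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(STOMACH_REGIONS, collapse = ", "), ")")
  invisible(TRUE)
}

# metadata rows aligned to the columns of a ProteomeMatrix
.alignMetadata <- function(pm, metadata) {
  metadata <- as.data.frame(metadata)
  if (!all(c("sample", "region") %in% colnames(metadata)))
    stop("metadata must contain columns 'sample' and 'region'")
  miss <- setdiff(colnames(pm), metadata$sample)
  if (length(miss))
    stop("samples missing from metadata: ", paste(utils::head(miss, 5), collapse = ", "))
  metadata[match(colnames(pm), metadata$sample), , drop = FALSE]
}
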