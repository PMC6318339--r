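#' Select outlier proteins as subtyping features
#'
#' A protein becomes a subtyping feature iff it is detected in at least
#' `ceil(min_detect_frac * n_patients)` patients and the fraction of
#' detecting patients in which it is called an outlier is at least
#' `min_outlier_frac`.  With the cohort size 58 and the default 20%, the
#' detection threshold is 12 patients.  The outlier-fraction denominator is
#' the number of detecting patients by default; set
#' `denominator = "all"` to divide by the full cohort instead.
#'
#' @param calls an [OutlierCalls-class] over the cohort.
#' @param detections logical sample x protein matrix of detections (e.g.
#'   `t(abundanceValues(q) > 0)`), or a named list of per-sample protein
#'   sets.
#' @param min_detect_frac minimum detection fraction (default 0.20).
#' @param min_outlier_frac minimum outlier fraction (default 0.75).
#' @param denominator `"detected"` (default) or `"all"`.
#' @return character vector of selected proteins.
#' @export
selectOutlierFeatures <- function(calls, detections, min_detect_frac = 0.20,
                                  min_outlier_frac = 0.75,
                                  denominator = c("detected", "all")) {
  denominator <- match.arg(denominator)
  cl <- outlierMatrix(calls)
  if (is.list(detections)) {
    det <- matrix(FALSE, nrow(cl), ncol(cl), dimnames = dimnames(cl))
    for (s in intersect(rownames(cl), names(detections)))
      det[s, ] <- colnames(cl) %in% detections[[s]]
  } else {
    det <- detections[rownames(cl), colnames(cl), drop = FALSE]
  }
  n <- nrow(cl)
  if (!n) stop("empty cohort")
  det_count <- colSums(det)
  out_count <- colSums(cl & det)
  denom <- if (denominator == "detected") det_count else n
  frac <- ifelse(denom > 0, out_count / denom, 0)
  keep <- det_count >= ceiling(min_detect_frac * n) & frac >= min_outlier_frac
  colnames(cl)[keep]
}

#' Resampling consensus clustering
#'
#' Re-implementation of hierarchical consensus clustering from its stated
#' parameters: in each of `reps` iterations a proportion `item_frac`
#' (default 90%) of the items (patients) is subsampled without replacement
#' and clustered by average-linkage hierarchical clustering of
#' 1 - Pearson correlation between item profiles, cut at each k in
#' `k_range`.  The consensus matrix entry for an item pair is its
#' co-clustering count divided by its co-sampling count.  Final assignments
#' per k come from average-linkage hierarchical clustering of
#' 1 - consensus.  Deterministic under `seed`.
#'
#' @param x numeric matrix, features x items (e.g. log2(iFOT + 0.01)
#'   profiles of the selected outlier proteins, columns = patients).
#' @param k_range integer cluster numbers to evaluate (default 2..10).
#' @param reps number of resampling iterations (default 500).
#' @param item_frac proportion of items per resample (default 0.9).
#' @param seed RNG seed.
#' @return a [SubtypeResult-class]; the chosen k is set by [chooseK()]
#'   with its default (delta-area) rule.
#' @export
consensusCluster <- function(x, k_range = 2:10, reps = 500L,
                             item_frac = 0.9, seed = 1L) {
  x <- as.matrix(x)
  n <- ncol(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("item%03d", seq_len(n))
  if (max(k_range) > n) stop("k exceeds the number of items")
  sds <- apply(x, 2, stats::sd)
  if (all(sds == 0)) stop("all item profiles are constant")
  m <- ceiling(item_frac * n)
  if (m < max(k_range)) stop("subsample size ", m, " is below max(k_range)")

  withSeed(seed, {
    co_sampled <- matrix(0, n, n)
    co_cluster <- array(0, dim = c(n, n, length(k_range)))
    for (r in seq_len(reps)) {
      idx <- sort(sample.int(n, m, replace = FALSE))
      co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
      d <- stats::as.dist(1 - stats::cor(x[, idx, drop = FALSE]))
      hc <- stats::hclust(d, method = "average")
      for (ki in seq_along(k_range)) {
        labs <- stats::cutree(hc, k = k_range[ki])
        same <- outer(labs, labs, `==`)
        co_cluster[idx, idx, ki] <- co_cluster[idx, idx, ki] + same
      }
    }
    consensus <- list()
    assign_mat <- matrix(NA_integer_, length(k_range), n,
                         dimnames = list(as.character(k_range), colnames(x)))
    for (ki in seq_along(k_range)) {
      cm <- co_cluster[, , ki] / ifelse(co_sampled > 0, co_sampled, 1)
      diag(cm) <- 1
      cm <- (cm + t(cm)) / 2   # guard against fp asymmetry
      dimnames(cm) <- list(colnames(x), colnames(x))
      consensus[[as.character(k_range[ki])]] <- cm
      hc2 <- stats::hclust(stats::as.dist(1 - cm), method = "average")
      assign_mat[ki, ] <- stats::cutree(hc2, k = k_range[ki])
    }
    res <- new("SubtypeResult", kRange = k_range, consensus = consensus,
               assignments = assign_mat, chosenK = k_range[1],
               seed = as.integer(seed),
               params = list(reps = as.integer(reps), item_frac = item_frac))
    res@chosenK <- chooseK(res)
    validObject(res)
    res
  })
}

#' Choose the number of clusters from consensus matrices
#'
#' Default rule: a stability-gated delta-area criterion.  With `A(k)` the
#' area under the empirical CDF of the off-diagonal consensus entries at k
#' (equal to 1 minus their mean), the relative change is
#' `delta(k_min) = A(k_min)` and `delta(k) = (A(k) - A(k-1)) / A(k-1)`.
#' Only k values whose clustering is stable — PAC (proportion of ambiguous
#' clustering, `F(0.9) - F(0.1)` of the consensus CDF) at most `pac_gate` —
#' compete; among those the k maximizing `delta` wins, ties going to the
#' smaller k.  When no k reaches stable consensus (structureless data) the
#' minimum k is returned.  The gate is needed because the raw delta-area
#' argmax is fooled on null data: average linkage splits off singletons at
#' small k, deflating `A(k_min)` and inflating the relative change just
#' above it.  `method = "pac"` instead minimizes PAC outright.
#'
#' @param result a [SubtypeResult-class].
#' @param method `"delta-area"` (default) or `"pac"`.
#' @param pac_limits lower/upper consensus bounds for PAC.
#' @param pac_gate maximum PAC for a k to count as stable under the
#'   delta-area rule (default 0.1).
#' @return the selected integer k.
#' @export
chooseK <- function(result, method = c("delta-area", "pac"),
                    pac_limits = c(0.1, 0.9), pac_gate = 0.1) {
  method <- match.arg(method)
  ks <- kRange(result)
  if (length(ks) == 1L) return(ks)
  offdiag <- function(cm) cm[lower.tri(cm)]
  if (method == "delta-area") {
    A <- vapply(as.character(ks), function(k)
      1 - mean(offdiag(consensusMatrix(result, k))), numeric(1))
    pac <- vapply(as.character(ks), function(k) {
      v <- offdiag(consensusMatrix(result, k))
      mean(v <= pac_limits[2]) - mean(v <= pac_limits[1])
    }, numeric(1))
    delta <- c(A[1], diff(A) / A[-length(A)])
    stable <- which(pac <= pac_gate)
    if (!length(stable)) return(min(ks))
    ks[stable[which.max(delta[stable])]]
  } else {
    pac <- vapply(as.character(ks), function(k) {
      v <- offdiag(consensusMatrix(result, k))
      mean(v <= pac_limits[2]) - mean(v <= pac_limits[1])
    }, numeric(1))
    ks[which.min(pac)]
  }
}

#' Summarize subtypes: members, outlier frequencies, clinical cross-tabs
#'
#' For the chosen (or a forced) k: per-subtype member lists, the
#' within-subtype outlier frequency of every called protein (the data
#' behind a subtype heatmap), and optional cross-tabulations of subtype
#' against stomach section and Lauren class when metadata provides them.
#'
#' @param result a [SubtypeResult-class].
#' @param calls the [OutlierCalls-class] the features came from.
#' @param metadata optional sample metadata (`sample`, `section` and/or
#'   `lauren`).
#' @param k cluster number (default `chosenK(result)`).
#' @return list: `members` (data.frame sample/subtype), `outlier_freq`
#'   (protein x subtype frequency matrix), `section_tab`, `lauren_tab`
#'   (tables or NULL).
#' @export
subtypeReport <- function(result, calls, metadata = NULL, k = NULL) {
  if (is.null(k)) k <- chosenK(result)
  labs <- assignments(result, k)
  cl <- outlierMatrix(calls)
  common <- intersect(names(labs), rownames(cl))
  members <- data.frame(sample = names(labs), subtype = as.integer(labs),
                        stringsAsFactors = FALSE)
  freq <- vapply(sort(unique(labs)), function(s) {
    ss <- intersect(names(labs)[labs == s], common)
    colMeans(cl[ss, , drop = FALSE])
  }, numeric(ncol(cl)))
  colnames(freq) <- paste0("subtype", sort(unique(labs)))
  section_tab <- lauren_tab <- NULL
  if (!is.null(metadata)) {
    md <- as.data.frame(metadata)
    md <- md[match(members$sample, md$sample), , drop = FALSE]
    if ("section" %in% colnames(md) && !all(is.na(md$section)))
      section_tab <- table(subtype = members$subtype, section = md$section)
    if ("lauren" %in% colnames(md) && !all(is.na(md$lauren)))
      lauren_tab <- table(subtype = members$subtype, lauren = md$lauren)
  }
  list(members = members, outlier_freq = freq,
       section_tab = section_tab, lauren_tab = lauren_tab)
}
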