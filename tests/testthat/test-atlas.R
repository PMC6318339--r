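test_that("detection frequency is the per-region detected fraction", {
  set.seed(3)
  vals <- matrix(rbinom(20 * 21, 1, 0.5) * rexp(20 * 21), 20, 21)
  fx <- makePM(vals, rep(STOMACH_REGIONS, 3))
  freq <- detectionFrequency(fx$pm, fx$metadata)
  expect_true(all(freq >= 0 & freq <= 1))
  # brute-force recount
  for (r in STOMACH_REGIONS) {
    cols <- fx$metadata$sample[fx$metadata$region == r]
    for (p in rownames(vals)[1:5])
      expect_identical(freq[p, r],
                       mean(abundanceValues(fx$pm)[p, cols] > 0))
  }
  # a protein detected in 9 of 12 samples of one region has frequency 0.75
  v2 <- matrix(0, 1, 12, dimnames = list("P", sprintf("x%02d", 1:12)))
  v2[1, 1:9] <- 1
  fx2 <- makePM(v2, "Ca")
  expect_identical(detectionFrequency(fx2$pm, fx2$metadata)["P", "Ca"], 0.75)
})

test_that("core proteome requires detection in every region", {
  freq <- matrix(0.5, 3, 7,
                 dimnames = list(c("core", "gap", "none"), STOMACH_REGIONS))
  freq["gap", "Py"] <- 0
  freq["none", ] <- 0
  expect_identical(coreProteome(freq), "core")
})

test_that("region-specific calls follow the 75/25 rule in both readings", {
  mk <- function(v) matrix(v, 1, 7, dimnames = list("P", STOMACH_REGIONS))
  f1 <- mk(c(rep(0.1, 6), 0.8)); colnames(f1) <- c(setdiff(STOMACH_REGIONS, "Py"), "Py")
  r1 <- callRegionSpecific(f1)
  expect_identical(r1$label, "region_enriched")
  expect_identical(r1$enriched_regions, "Py")

  f2 <- mk(0.2); f2[1, c("Py", "An")] <- 0.8
  r2 <- callRegionSpecific(f2)
  expect_identical(r2$label, "region_enriched")
  expect_setequal(strsplit(r2$enriched_regions, ",")[[1]], c("Py", "An"))

  f3 <- mk(c(0.8, 0.8, 0.8, rep(0.1, 4)))
  expect_identical(callRegionSpecific(f3)$label, "other")

  # gap-zone frequencies break the strict reading but can pass the loose one
  f4 <- mk(c(0.8, 0.5, rep(0.1, 5)))
  expect_identical(callRegionSpecific(f4, rule = "strict")$label, "other")
  expect_identical(callRegionSpecific(f4, rule = "loose")$label,
                   "region_enriched")
})

test_that("region-specific calls equal the brute-force rule on random tables", {
  set.seed(5)
  freq <- matrix(sample(seq(0, 1, 0.05), 1000 * 7, replace = TRUE), 1000, 7,
                 dimnames = list(sprintf("P%04d", 1:1000), STOMACH_REGIONS))
  for (rule in c("strict", "loose")) {
    got <- callRegionSpecific(freq, rule = rule)
    for (i in seq_len(nrow(freq))) {
      want <- oracleRegionSpecific(freq[i, ], rule = rule)
      if (length(want)) {
        expect_identical(got$label[i], "region_enriched")
        expect_setequal(strsplit(got$enriched_regions[i], ",")[[1]], want)
      } else {
        expect_identical(got$label[i], "other")
      }
    }
  }
})

test_that("region correlations are symmetric with unit diagonal", {
  set.seed(9)
  vals <- matrix(rexp(300 * 21), 300, 21)
  fx <- makePM(vals, rep(STOMACH_REGIONS, 3))
  out <- regionCorrelationSections(fx$pm, fx$metadata)
  expect_equal(out$correlation, t(out$correlation))
  expect_equal(unname(diag(out$correlation)), rep(1, 7))
  expect_identical(sort(unique(out$sections)), c(1L, 2L))

  # two regions fed identical samples correlate perfectly
  v2 <- vals
  ai <- fx$metadata$region == "AI"; py <- fx$metadata$region == "Py"
  v2[, py] <- v2[, ai]
  fx2 <- makePM(v2, fx$metadata$region)
  expect_equal(regionCorrelationSections(fx2$pm, fx2$metadata)$correlation["AI", "Py"], 1)
})

test_that("the planted section bipartition is recovered", {
  cfg <- smallConfig(seed = 12, samples_per_region = c(Ca = 6, Fu = 6, LC = 6,
                                                       GC = 6, AI = 6, An = 6,
                                                       Py = 6))
  ref <- simulateReferenceCohort(cfg)
  pp <- preprocessCohort(ref$matrix, ref$evidence, ref$metadata)
  secs <- regionCorrelationSections(pp$ifot, ref$metadata)$sections
  expect_setequal(names(secs)[secs == secs[["Ca"]]], PROXIMAL_REGIONS)
  expect_setequal(names(secs)[secs == secs[["Py"]]], DISTAL_REGIONS)
})

test_that("section markers flag planted fourfold-plus differences", {
  set.seed(4)
  n <- 60
  vals <- matrix(10^(3 + matrix(rnorm(n * 20, sd = 0.1), n, 20)), n, 20)
  rownames(vals) <- sprintf("P%03d", 1:n)
  regions <- rep(STOMACH_REGIONS[c(1, 5)], each = 10)   # Ca (prox), AI (dist)
  prox <- 1:10
  vals["P001", prox] <- vals["P001", prox] * 16         # 16-fold proximal
  vals["P002", -prox] <- vals["P002", -prox] * 16       # 16-fold distal
  fx <- makePM(vals, regions)
  mk <- sectionMarkers(fx$pm, fx$metadata)
  expect_identical(mk$direction[mk$protein_id == "P001"], "proximal")
  expect_identical(mk$direction[mk$protein_id == "P002"], "distal")
  # identical group distributions are not flagged
  expect_true(all(mk$direction[!mk$protein_id %in% c("P001", "P002")] == "ns"))
})

test_that("section-marker p-values match the textbook Student t", {
  set.seed(6)
  vals <- matrix(10^(2 + rnorm(50 * 12, sd = 0.4)), 50, 12,
                 dimnames = list(sprintf("P%03d", 1:50), NULL))
  regions <- rep(c("Fu", "An"), each = 6)
  fx <- makePM(vals, regions)
  mk <- sectionMarkers(fx$pm, fx$metadata, pseudocount = 0.01)
  lg <- log2(abundanceValues(fx$pm) + 0.01)
  prox <- fx$metadata$section == "proximal"
  for (p in mk$protein_id) {
    expect_equal(mk$p[mk$protein_id == p],
                 oracleStudentT(lg[p, prox], lg[p, !prox]),
                 tolerance = 1e-12)
  }
})

test_that("co-expression modules recover planted blocks and apply the
           abundance gate", {
  # three blocks of region-median profiles, zero within-block noise
  protos <- rbind(c(9, 9, 9, 1, 1, 1, 1),
                  c(1, 9, 1, 9, 1, 9, 1),
                  c(1, 1, 1, 1, 9, 9, 9))
  vals <- matrix(0, 31, 14)
  rownames(vals) <- sprintf("P%03d", 1:31)
  block <- rep(1:3, each = 10)
  for (i in 1:30) vals[i, ] <- rep(protos[block[i], ], each = 2)
  vals[31, ] <- 0.5   # below the median-iFOT gate everywhere
  fx <- makePM(vals, rep(STOMACH_REGIONS, each = 2))
  mods <- coexpressionModules(fx$pm, fx$metadata, n_modules = 3)
  expect_false("P031" %in% names(mods))
  expect_identical(mclust::adjustedRandIndex(mods, block[1:30]), 1)
  # identical profiles always share a module
  expect_identical(unname(mods["P001"]), unname(mods["P002"]))
})

test_that("per-protein CV is computed over detected values", {
  vals <- matrix(c(5, 5, 5, 5,
                   1, 3, 0, 0,
                   2, 0, 0, 0), 3, 4, byrow = TRUE,
                 dimnames = list(c("const", "pair", "single"), NULL))
  fx <- makePM(vals, "Ca")
  cv <- proteinCV(fx$pm)
  expect_identical(unname(cv$cv["const"]), 0)
  expect_equal(unname(cv$cv["pair"]), 70.71, tolerance = 1e-3)
  expect_true(is.na(cv$cv["single"]))
  # brute force on a random matrix
  set.seed(8)
  r <- matrix(rexp(40) * rbinom(40, 1, 0.7), 8, 5)
  rownames(r) <- sprintf("P%d", 1:8)
  got <- proteinCV(makePM(r, "Fu")$pm)$cv
  for (i in 1:8) {
    x <- r[i, ][r[i, ] > 0]
    want <- if (length(x) >= 2) 100 * sd(x) / mean(x) else NA_real_
    expect_equal(unname(got[i]), want)
  }
})

test_that("signature summaries stratify by class and section", {
  vals <- matrix(c(1, 2, 3, 10, 20, 30), 1, 6,
                 dimnames = list("G1", sprintf("s%d", 1:6)))
  md <- data.frame(sample = colnames(vals), subject = colnames(vals),
                   region = rep(c("Ca", "Py"), each = 3),
                   tissue_class = rep(c("N", "T"), 3))
  md$section <- regionSection(md$region)
  pm <- ProteomeMatrix(vals, "ifot")
  out <- signatureSummary(pm, md, "G1")
  n_prox <- out[out$tissue_class == "N" & out$section == "proximal", ]
  expect_identical(n_prox$median, median(c(1, 3)))
  expect_error(signatureSummary(pm, md, "ABSENT"), "no overlap")
})

test_that("a planted boosted signature separates tumor from normal medians", {
  cfg <- smallConfig(seed = 14)
  ref <- simulateReferenceCohort(cfg)
  tum <- simulateTumorCohort(cfg, ref$truth)
  sig <- tum$truth$outlier_signature[[1]]
  both <- cbind(abundanceValues(ref$matrix), abundanceValues(tum$tumor))
  md <- rbind(ref$metadata[, c("sample", "subject", "region", "tissue_class", "section")],
              tum$metadata[tum$metadata$tissue_class == "T",
                           c("sample", "subject", "region", "tissue_class", "section")])
  pm <- computeIFOT(computeFOT(ProteomeMatrix(both, "ibaq")))
  out <- signatureSummary(pm, md, sig)
  t_med <- median(out$median[out$tissue_class == "T"])
  n_med <- median(out$median[out$tissue_class == "N"])
  expect_gt(t_med, n_med)
})

test_that("detection statistics are invariant to monotone rescaling", {
  set.seed(10)
  vals <- matrix(rbinom(140, 1, 0.6) * rexp(140), 10, 14)
  rownames(vals) <- sprintf("P%02d", 1:10)
  fx <- makePM(vals, rep(STOMACH_REGIONS, 2))
  fx2 <- makePM(sqrt(vals) * 100, rep(STOMACH_REGIONS, 2))
  expect_identical(detectionFrequency(fx$pm, fx$metadata),
                   detectionFrequency(fx2$pm, fx2$metadata))
})
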