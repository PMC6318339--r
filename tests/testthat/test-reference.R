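test_that("reference intervals use type-7 percentiles and the printed formula", {
  md <- data.frame(sample = sprintf("s%03d", 1:100),
                   subject = sprintf("s%03d", 1:100),
                   region = "Ca", tissue_class = "N")
  m <- matrix(1:100, 1, 100, dimnames = list("P1", md$sample))
  ri <- riTable(buildReferenceIntervals(ProteomeMatrix(m, "ifot"), md))
  # frozen values from the order-statistic interpolation oracle
  expect_equal(ri$p10, oraclePercentile(1:100, 0.1))   # 10.9
  expect_equal(ri$p90, oraclePercentile(1:100, 0.9))   # 90.1
  expect_equal(ri$p10, 10.9)
  expect_equal(ri$p90, 90.1)
  expect_equal(ri$upper, 327.7)

  # degenerate: all reference values equal v -> upper = v
  m2 <- matrix(7, 1, 100, dimnames = list("P1", md$sample))
  ri2 <- riTable(buildReferenceIntervals(ProteomeMatrix(m2, "ifot"), md))
  expect_identical(ri2$upper, 7)

  # direct substitution: p10 = 1, p90 = 2 -> upper = 5
  x <- c(0.5, 1, seq(1.1, 1.9, length.out = 7), 2, 2.5)   # 11 sorted values
  m3 <- matrix(x, 1, 11, dimnames = list("P1", md$sample[1:11]))
  ri3 <- riTable(buildReferenceIntervals(ProteomeMatrix(m3, "ifot"), md[1:11, ]))
  expect_equal(ri3$p10, 1)
  expect_equal(ri3$p90, 2)
  expect_equal(ri3$upper, 5)
})

test_that("the RI formula and ordering hold for every protein of a cohort", {
  cfg <- smallConfig(seed = 5)
  ref <- simulateReferenceCohort(cfg)
  pp <- preprocessCohort(ref$matrix, ref$evidence, ref$metadata)
  ri <- riTable(buildReferenceIntervals(pp$ifot, ref$metadata))
  def <- ri$defined
  expect_true(all(ri$p10[def] <= ri$p90[def]))
  expect_true(all(ri$upper[def] >= ri$p90[def]))
  expect_equal(ri$upper[def], ri$p90[def] + 3 * (ri$p90[def] - ri$p10[def]))
  eqcase <- def & ri$p10 == ri$p90
  expect_true(all(ri$upper[eqcase] == ri$p90[eqcase]))
  # percentiles agree with the independent oracle
  a <- abundanceValues(pp$ifot)
  for (p in sample(rownames(a), 25)) {
    i <- which(ri$protein_id == p)
    expect_equal(ri$p10[i], oraclePercentile(a[p, ], 0.1))
    expect_equal(ri$p90[i], oraclePercentile(a[p, ], 0.9))
  }
})

test_that("outlier calls use a strict upper-limit inequality", {
  md <- data.frame(sample = sprintf("s%02d", 1:20),
                   subject = sprintf("s%02d", 1:20),
                   region = "Fu", tissue_class = "N")
  set.seed(2)
  m <- matrix(10 + rnorm(20), 1, 20, dimnames = list("P1", md$sample))
  ri <- buildReferenceIntervals(ProteomeMatrix(m, "ifot"), md)
  up <- riTable(ri)$upper
  q <- matrix(c(up, up + 1e-9, up - 1e-9), 1, 3,
              dimnames = list("P1", c("at", "above", "below")))
  calls <- callOutliers(ProteomeMatrix(q, "ifot"), ri)
  expect_identical(unname(outlierMatrix(calls)[, "P1"]),
                   c(FALSE, TRUE, FALSE))
  expect_identical(unname(outlierCounts(calls)),
                   c(0L, 1L, 0L))
})

test_that("proteins without a defined RI are never called", {
  md <- data.frame(sample = sprintf("s%02d", 1:12),
                   subject = sprintf("s%02d", 1:12),
                   region = "GC", tissue_class = "N")
  m <- matrix(c(rep(1, 12), rep(0, 9), 5, 6, 7), 2, 12, byrow = TRUE,
              dimnames = list(c("full", "sparse"), md$sample))
  ri <- buildReferenceIntervals(ProteomeMatrix(m, "ifot"), md,
                                min_ref = 10, detected_only = TRUE)
  expect_identical(riTable(ri)$defined, c(TRUE, FALSE))
  q <- matrix(1e6, 2, 1, dimnames = list(c("full", "sparse"), "q1"))
  calls <- callOutliers(ProteomeMatrix(q, "ifot"), ri)
  expect_true(outlierMatrix(calls)["q1", "full"])
  expect_false(outlierMatrix(calls)["q1", "sparse"])
})

test_that("outlier calling is monotone in each coordinate", {
  set.seed(13)
  md <- data.frame(sample = sprintf("s%02d", 1:30),
                   subject = sprintf("s%02d", 1:30),
                   region = "An", tissue_class = "N")
  m <- matrix(rexp(10 * 30), 10, 30,
              dimnames = list(sprintf("P%02d", 1:10), md$sample))
  ri <- buildReferenceIntervals(ProteomeMatrix(m, "ifot"), md)
  q <- matrix(rexp(10 * 5), 10, 5,
              dimnames = list(rownames(m), sprintf("q%d", 1:5)))
  base_calls <- outlierMatrix(callOutliers(ProteomeMatrix(q, "ifot"), ri))
  for (rep in 1:40) {
    q2 <- q
    i <- sample(10, 1); j <- sample(5, 1)
    q2[i, j] <- q2[i, j] + rexp(1, rate = 0.2)   # raise one value
    new_calls <- outlierMatrix(callOutliers(ProteomeMatrix(q2, "ifot"), ri))
    expect_true(all(new_calls >= base_calls))    # no call flips off
  }
  # explicit flips at the boundary
  up <- riTable(ri)$upper[1]
  q3 <- q; q3[1, 1] <- up + 1
  expect_true(outlierMatrix(callOutliers(ProteomeMatrix(q3, "ifot"), ri))[1, 1])
  q3[1, 1] <- up - min(1, up / 2)
  expect_false(outlierMatrix(callOutliers(ProteomeMatrix(q3, "ifot"), ri))[1, 1])
})

test_that("calls agree with a direct comparison oracle on random instances", {
  set.seed(17)
  md <- data.frame(sample = sprintf("s%02d", 1:15),
                   subject = sprintf("s%02d", 1:15),
                   region = "LC", tissue_class = "N")
  for (rep in 1:10) {
    m <- matrix(rexp(8 * 15) * rbinom(8 * 15, 1, 0.8), 8, 15,
                dimnames = list(sprintf("P%d", 1:8), md$sample))
    ri <- buildReferenceIntervals(ProteomeMatrix(m, "ifot"), md)
    q <- matrix(rexp(8 * 4, rate = 0.3), 8, 4,
                dimnames = list(rownames(m), sprintf("q%d", 1:4)))
    got <- outlierMatrix(callOutliers(ProteomeMatrix(q, "ifot"), ri))
    want <- t(q > riTable(ri)$upper)
    expect_identical(unname(got), unname(want))
  }
})

test_that("subsampling summaries are deterministic and shrink with depth", {
  cfg <- smallConfig(seed = 7)
  ref <- simulateReferenceCohort(cfg)
  pp <- preprocessCohort(ref$matrix, ref$evidence, ref$metadata)
  s1 <- subsampleStability(pp$ifot, fractions = c(0.1, 0.4, 0.8),
                           reps = 40, seed = 5)
  s2 <- subsampleStability(pp$ifot, fractions = c(0.1, 0.4, 0.8),
                           reps = 40, seed = 5)
  expect_identical(s1, s2)
  expect_gt(s1$mean_iqr[1], s1$mean_iqr[3])
  # the full cohort without replacement has no resampling variability
  s3 <- subsampleStability(pp$ifot, fractions = 1, reps = 10, seed = 1,
                           replace = FALSE)
  expect_identical(s3$mean_iqr, 0)
  expect_error(subsampleStability(pp$ifot, fractions = -0.2), "fractions")
})
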