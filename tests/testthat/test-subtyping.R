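test_that("feature selection applies the 20%-detected / 75%-outlier rule", {
  n <- 58
  samples <- sprintf("pt%02d", 1:n)
  prot <- c("kept", "few_detect", "low_frac")
  det <- matrix(FALSE, n, 3, dimnames = list(samples, prot))
  cl <- matrix(FALSE, n, 3, dimnames = list(samples, prot))
  det[1:12, "kept"] <- TRUE; cl[1:9, "kept"] <- TRUE          # 12 >= 12; 9/12 = 0.75
  det[1:11, "few_detect"] <- TRUE; cl[1:11, "few_detect"] <- TRUE  # 11 < ceil(0.2*58)
  det[1:20, "low_frac"] <- TRUE; cl[1:14, "low_frac"] <- TRUE  # 14/20 = 0.70 < 0.75
  calls <- new("OutlierCalls", calls = cl,
               counts = stats::setNames(as.integer(rowSums(cl)), samples))
  expect_identical(selectOutlierFeatures(calls, det), "kept")
})

test_that("feature selection equals brute-force set evaluation", {
  set.seed(19)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    p <- 12
    samples <- sprintf("s%02d", 1:n)
    prot <- sprintf("P%02d", 1:p)
    det <- matrix(runif(n * p) < 0.4, n, p, dimnames = list(samples, prot))
    cl <- det & matrix(runif(n * p) < 0.7, n, p)
    calls <- new("OutlierCalls", calls = cl,
                 counts = stats::setNames(as.integer(rowSums(cl)), samples))
    got <- selectOutlierFeatures(calls, det)
    want <- prot[vapply(prot, function(pp) {
      d <- sum(det[, pp])
      d >= ceiling(0.2 * n) && d > 0 && sum(cl[, pp] & det[, pp]) / d >= 0.75
    }, logical(1))]
    expect_identical(got, want)
  }
})

test_that("consensus matrices satisfy their structural invariants", {
  set.seed(23)
  x <- matrix(rnorm(20 * 15), 20, 15)
  res <- consensusCluster(x, k_range = 2:4, reps = 30, seed = 3)
  for (k in 2:4) {
    cm <- consensusMatrix(res, k)
    expect_equal(cm, t(cm))
    expect_equal(unname(diag(cm)), rep(1, 15))
    expect_true(all(cm >= 0 & cm <= 1))
    labs <- assignments(res, k)
    expect_identical(length(unique(labs)), as.integer(k))
  }
})

test_that("full sampling with deterministic base clustering is binary", {
  set.seed(29)
  x <- matrix(rnorm(12 * 10), 12, 10)
  res <- consensusCluster(x, k_range = 2:3, reps = 25, item_frac = 1, seed = 1)
  for (k in 2:3) {
    cm <- consensusMatrix(res, k)
    expect_true(all(cm %in% c(0, 1)))
  }
})

test_that("degenerate and separable geometries behave as constructed", {
  # n = 3 items at k = 3: every item is its own cluster
  x <- matrix(rnorm(30), 10, 3)
  res <- consensusCluster(x, k_range = 3, reps = 10, item_frac = 1, seed = 2)
  expect_identical(sort(unname(assignments(res, 3))), 1:3)
  expect_equal(unname(diag(consensusMatrix(res, 3))), rep(1, 3))

  # two correlation-separable clouds: exact {0,1} block consensus
  proto <- cbind(c(rep(1, 5), rep(5, 5)), c(rep(5, 5), rep(1, 5)))
  set.seed(31)
  x2 <- proto[, rep(1:2, each = 6)] + matrix(rnorm(120, sd = 0.01), 10, 12)
  colnames(x2) <- sprintf("i%02d", 1:12)
  res2 <- consensusCluster(x2, k_range = 2, reps = 40, seed = 5)
  cm <- consensusMatrix(res2, 2)
  truth <- rep(1:2, each = 6)
  expect_true(all(cm[truth == 1, truth == 1] == 1))
  expect_true(all(cm[truth == 2, truth == 2] == 1))
  expect_true(all(cm[truth == 1, truth == 2] == 0))

  expect_error(consensusCluster(matrix(1, 5, 8), k_range = 2),
               "constant")
  expect_error(consensusCluster(matrix(rnorm(40), 5, 8), k_range = 2:9),
               "exceeds the number of items")
  expect_error(consensusCluster(matrix(rnorm(40), 5, 8), k_range = 2:6,
                                item_frac = 0.5),
               "below max")
})

test_that("chooseK finds planted k, falls back to minimum k on noise", {
  set.seed(37)
  proto <- matrix(rnorm(60), 20, 3)
  x <- proto[, rep(1:3, each = 10)] + matrix(rnorm(600, sd = 0.1), 20, 30)
  res <- consensusCluster(x, k_range = 2:6, reps = 50, seed = 7)
  expect_identical(chosenK(res), 3L)

  noise <- matrix(rnorm(40 * 30), 40, 30)
  res_n <- consensusCluster(noise, k_range = 2:6, reps = 50, seed = 8)
  expect_identical(chosenK(res_n), 2L)

  res_single <- consensusCluster(x, k_range = 4, reps = 10, seed = 9)
  expect_identical(chooseK(res_single), 4L)
})

test_that("assignments are invariant to item order up to relabeling", {
  set.seed(41)
  proto <- matrix(rnorm(40), 20, 2)
  x <- proto[, rep(1:2, each = 8)] + matrix(rnorm(320, sd = 0.05), 20, 16)
  colnames(x) <- sprintf("i%02d", 1:16)
  res_a <- consensusCluster(x, k_range = 2, reps = 40, seed = 11)
  perm <- sample(16)
  res_b <- consensusCluster(x[, perm], k_range = 2, reps = 40, seed = 12)
  la <- assignments(res_a, 2)
  lb <- assignments(res_b, 2)[names(la)]
  expect_identical(mclust::adjustedRandIndex(la, lb), 1)
})

test_that("subtype reports cross-tabulate members and outlier frequencies", {
  n <- 12
  samples <- sprintf("pt%02d", 1:n)
  prot <- sprintf("P%02d", 1:6)
  truth <- rep(1:2, each = 6)
  cl <- matrix(FALSE, n, 6, dimnames = list(samples, prot))
  cl[truth == 1, 1:3] <- TRUE
  cl[truth == 2, 4:6] <- TRUE
  calls <- new("OutlierCalls", calls = cl,
               counts = stats::setNames(as.integer(rowSums(cl)), samples))
  x <- rbind(matrix(as.numeric(t(cl)) * 8, 6, n) +
               matrix(rnorm(6 * n, sd = 0.05), 6, n))
  colnames(x) <- samples
  res <- consensusCluster(x, k_range = 2, reps = 30, seed = 13)
  md <- data.frame(sample = samples, subject = samples,
                   region = rep(c("Ca", "Py"), 6), tissue_class = "T",
                   lauren = rep(c("diffuse", "intestinal"), each = 6))
  md$section <- regionSection(md$region)
  rep_out <- subtypeReport(res, calls, md, k = 2)
  labs <- assignments(res, 2)
  expect_identical(mclust::adjustedRandIndex(labs, truth), 1)
  # within-subtype outlier frequency ~1 on the own signature, 0 elsewhere
  own <- rep_out$outlier_freq[1:3, paste0("subtype", labs[["pt01"]])]
  other <- rep_out$outlier_freq[4:6, paste0("subtype", labs[["pt01"]])]
  expect_true(all(own == 1))
  expect_true(all(other == 0))
  expect_identical(unname(rowSums(rep_out$section_tab)),
                   unname(as.numeric(table(labs))))
  expect_identical(unname(rowSums(rep_out$lauren_tab)),
                   unname(as.numeric(table(labs))))
  rep_nolab <- subtypeReport(res, calls, metadata = NULL, k = 2)
  expect_null(rep_nolab$section_tab)
  expect_null(rep_nolab$lauren_tab)
})
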