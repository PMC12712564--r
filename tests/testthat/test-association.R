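# Clustering partitions, cross-tabulation, Fisher exact test, FDR.

test_that("hierarchical partition separates well-separated groups", {
  coords <- matrix(c(0, 1, 10, 11), dimnames = list(2008:2011, NULL))
  p <- hierarchical_partition(coords, k = 2)
  expect_equal(unname(p$cluster), c(1, 1, 2, 2))
  expect_error(hierarchical_partition(coords, k = 1),
               class = "parameter_error")
  expect_error(hierarchical_partition(coords, k = 4),
               class = "parameter_error")

  # Degenerate: identical points still give a deterministic k = 2 cut.
  same <- matrix(1, 4, 2, dimnames = list(2008:2011, NULL))
  p2 <- hierarchical_partition(same, k = 2)
  expect_equal(p2$k, 2)
  expect_length(unique(p2$cluster), 2)
})

test_that("planted Gaussian year-clusters are recovered by both methods in 100 seeds", {
  miss_h <- 0L; miss_k <- 0L
  for (r in 1:100) {
    set.seed(6000 + r)
    sep <- 5
    centers <- rbind(c(0, 0, 0), c(sep, 0, 0))
    truth <- rep(1:2, each = 6)
    coords <- centers[truth, ] + matrix(rnorm(36, sd = 0.1 * sep), 12)
    rownames(coords) <- 2008:2019
    ph <- hierarchical_partition(coords, 2)$cluster
    pk <- kmeans_partition(coords, 2)$cluster
    if (length(unique(paste(ph, truth))) != 2) miss_h <- miss_h + 1L
    if (length(unique(paste(pk, truth))) != 2) miss_k <- miss_k + 1L
  }
  expect_identical(miss_h, 0L)
  expect_identical(miss_k, 0L)
})

test_that("k-means uses first/last-year centroids and rejects degenerate init", {
  coords <- rbind(matrix(rnorm(12, 0, 0.1), 6),
                  matrix(rnorm(12, 5, 0.1), 6))
  rownames(coords) <- 2008:2019
  p <- kmeans_partition(coords, 2)
  expect_equal(unname(p$cluster), rep(1:2, each = 6))

  same <- matrix(1, 12, 2, dimnames = list(2008:2019, NULL))
  expect_error(kmeans_partition(same, 2), class = "degenerate_init_error")
  expect_error(kmeans_partition(coords, 3), class = "parameter_error")
})

test_that("elbow curve is monotone and flags planted two-cluster structure", {
  set.seed(60)
  coords <- rbind(matrix(rnorm(12, 0, 0.2), 6),
                  matrix(rnorm(12, 8, 0.2), 6))
  rownames(coords) <- 2008:2019
  e <- elbow_k(coords, k_max = 6)
  expect_equal(e$k, 2L)
  expect_true(all(diff(e$curve$dispersion) <= 1e-9))
  expect_error(elbow_k(coords, k_max = 2), class = "parameter_error")

  # Uniform points: no structural guarantee, but the curve stays monotone.
  set.seed(61)
  u <- matrix(runif(24), 12, dimnames = list(2008:2019, NULL))
  eu <- elbow_k(u, k_max = 6)
  expect_true(all(diff(eu$curve$dispersion) <= 1e-9))
})

test_that("cross_tab reproduces the two-era worked example", {
  years <- 2008:2019
  # Data partition: 2008-2014 vs 2015-2019; performance: 2008-2013 vs
  # 2014-2019.
  a <- manual_partition(years, ifelse(years <= 2014, 1, 2))
  b <- manual_partition(years, ifelse(years <= 2013, 1, 2))
  tab <- cross_tab(a, b)
  expect_equal(unname(tab$counts), rbind(c(6, 1), c(0, 5)))
  expect_equal(sum(tab$counts), 12)

  expect_equal(unname(cross_tab(a, a)$counts), diag(c(7, 5)))
  b_short <- manual_partition(2008:2018, rep(1:2, c(6, 5)))
  expect_error(cross_tab(a, b_short), class = "alignment_error")
})

test_that("fisher_exact matches enumeration and closed forms", {
  expect_equal(fisher_exact(rbind(c(6, 1), c(0, 5))), 14 / 924,
               tolerance = 1e-9)
  expect_equal(fisher_exact(rbind(c(6, 0), c(0, 6))), 2 / 924,
               tolerance = 1e-12)
  expect_equal(fisher_exact(rbind(c(1, 0), c(0, 1))), 1.0)
  expect_warning(p0 <- fisher_exact(rbind(c(0, 0), c(3, 4))), "degenerate")
  expect_equal(p0, 1)
  expect_error(fisher_exact(matrix(1, 3, 3)), class = "parameter_error")
})

test_that("fisher_exact agrees with brute force and stats::fisher.test on 500 random tables", {
  set.seed(62)
  for (r in 1:500) {
    n <- sample(4:30, 1)
    tab <- matrix(stats::rmultinom(1, n, runif(4, 0.05, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact(tab)
    expect_equal(p, fisher_brute(tab), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.2, 0.8, 0.04)
  expect_true(all(fdr_adjust(p) >= p))
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "range_error")
})

test_that("association p-values are invariant to cluster relabeling", {
  set.seed(63)
  blocks <- rep(1:2, each = 6)
  Mb <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.85, 0.55)) +
    matrix(rnorm(144, sd = 0.02), 12)
  Mb <- pmin(pmax((Mb + t(Mb)) / 2, 0), 1)
  dimnames(Mb) <- list(2008:2019, 2008:2019)
  em <- structure(list(metric = "roc_auc", M = Mb, labels = 2008:2019,
                       thresholded = FALSE), class = "eval_matrix")
  part1 <- manual_partition(2008:2019, blocks)
  part2 <- manual_partition(2008:2019, 3 - blocks)   # labels swapped
  a1 <- associate(part1, list(roc_auc = em), "hierarchical")
  a2 <- associate(part2, list(roc_auc = em), "hierarchical")
  expect_equal(a1$p_raw, a2$p_raw)
  expect_true(all(a1$p_adjusted >= a1$p_raw))
})
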