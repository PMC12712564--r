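# Yearly model grid: splits, metrics, Youden thresholds, interyear
# evaluation.

test_that("splits follow the 56/24/20 stratified design and are seeded", {
  set.seed(50)
  b <- list(
    `2008` = data.frame(outcome = rep(c(0L, 1L), c(90, 10)),
                        x = rnorm(100)),
    `2009` = data.frame(outcome = rep(c(0L, 1L), c(80, 20)),
                        x = rnorm(100))
  )
  sp <- make_splits(b, seed = 3)
  for (yr in names(b)) {
    idx <- sp[[yr]]
    expect_equal(length(idx$test), 20)
    expect_equal(length(idx$validation), 24)
    expect_equal(length(idx$train), 56)
    all_idx <- c(idx$train, idx$validation, idx$test)
    expect_equal(sort(all_idx), 1:100)          # disjoint and exhaustive
    # Stratification preserves prevalence within one positive.
    prev <- mean(b[[yr]]$outcome)
    expect_lte(abs(sum(b[[yr]]$outcome[idx$test]) - prev * 20), 1)
  }
  expect_identical(make_splits(b, seed = 3), sp)
  expect_false(identical(make_splits(b, seed = 4), sp))

  b$`2008`$outcome <- 0L
  expect_error(make_splits(b, seed = 3), "2008", class = "split_error")
})

test_that("ROC-AUC and PR-AUC agree with pROC on random score sets", {
  set.seed(51)
  for (r in 1:20) {
    y <- rbinom(80, 1, 0.3)
    if (length(unique(y)) < 2) next
    s <- runif(80)
    expect_equal(roc_auc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
  # PR-AUC sanity: perfect ranking gives 1; reversed ranking is low.
  y <- c(0, 0, 0, 1, 1)
  expect_equal(pr_auc(c(0.1, 0.2, 0.3, 0.8, 0.9), y), 1)
  expect_lt(pr_auc(c(0.9, 0.8, 0.7, 0.2, 0.1), y), 0.5)
  expect_true(is.na(roc_auc(runif(5), rep(1, 5))))
})

test_that("Youden threshold matches brute-force candidate evaluation", {
  # Hand example: perfect separation at 0.6.
  yt <- youden_threshold(c(0.2, 0.3, 0.6, 0.9), c(0, 0, 1, 1))
  expect_equal(yt$threshold, 0.6)
  expect_equal(yt$J, 1)

  # Perfectly anti-separated: max J is 0 at some candidate.
  yt2 <- youden_threshold(c(0.9, 0.8, 0.1, 0.2), c(0, 0, 1, 1))
  expect_equal(yt2$J, 0)

  # Random cases against an exhaustive oracle.
  set.seed(52)
  for (r in 1:25) {
    s <- round(runif(40), 2); y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    cand <- sort(unique(s))
    J <- vapply(cand, function(c) {
      mean(s[y == 1] >= c) + mean(s[y == 0] < c) - 1
    }, 0)
    expect_equal(yt <- youden_threshold(s, y)$threshold,
                 cand[which(J == max(J))[1]])
  }

  # Duplicating the dataset leaves the threshold unchanged.
  s <- c(0.2, 0.5, 0.7, 0.9); y <- c(0, 1, 0, 1)
  expect_equal(youden_threshold(rep(s, 2), rep(y, 2))$threshold,
               youden_threshold(s, y)$threshold)
  expect_error(youden_threshold(s, rep(1, 4)), class = "threshold_error")
})

test_that("grid search never picks a gross underfit on separable data", {
  # One informative feature separates the classes; depth-1/5-tree models
  # lose to the reference configuration.
  set.seed(53)
  b <- lapply(stats::setNames(2008:2010, 2008:2010), function(y) {
    n <- 120
    x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
    out <- as.integer(x1 + 0.5 * x2 * x3 + rnorm(n, sd = 0.3) > 0)
    df <- data.frame(outcome = out, year = y, age = rnorm(n, 60, 10),
                     gender = factor(sample(c("F", "M"), n, TRUE)),
                     ethnicity = factor(sample(c("A", "B"), n, TRUE)))
    df$chapter.X1 <- as.integer(x1 > 0)
    df$chapter.X2 <- as.integer(x2 > 0)
    df$chapter.X3 <- as.integer(x3 > 0)
    df
  })
  sp <- make_splits(b, seed = 1)
  grid <- data.frame(n_trees = c(5L, 200L), max_depth = c(1L, 6L))
  sel <- select_hyperparameters(b, sp, "random_forest", grid, seed = 2)
  expect_equal(sel$n_trees, 200L)

  # Single-point grid returns unchanged.
  one <- data.frame(n_trees = 50L, max_depth = 3L)
  sel1 <- select_hyperparameters(b, sp, "random_forest", one, seed = 2)
  expect_equal(sel1$n_trees, 50L)
  expect_equal(sel1$max_depth, 3L)
})

test_that("interyear evaluation uses held-out test rows and both algorithms run", {
  batches <- make_batches("null", n_per_year = 120, seed = 19)
  sp <- make_splits(batches, seed = 4)
  # No leakage: training indices never intersect any test indices.
  for (yr in names(batches)) {
    expect_length(intersect(sp[[yr]]$train, sp[[yr]]$test), 0)
    expect_length(intersect(sp[[yr]]$validation, sp[[yr]]$test), 0)
  }
  for (algo in c("random_forest", "gradient_boosting")) {
    ms <- fit_yearly_models(batches, sp, algo, n_trees = 30L,
                            max_depth = 3L, seed = 5)
    expect_true(all(ms$thresholds > 0 & ms$thresholds < 1))
    ev <- interyear_evaluation(ms, batches, sp,
                               metric = c("roc_auc", "accuracy"))
    M <- ev$roc_auc$M
    expect_equal(dim(M), c(12, 12))
    expect_true(all(M >= 0 & M <= 1, na.rm = TRUE))
    # Each test column uses exactly the year's 20% test rows.
    expect_equal(unname(ev$roc_auc$n_test),
                 vapply(names(batches), function(yr) {
                   length(sp[[yr]]$test)
                 }, 0L, USE.NAMES = FALSE))
  }
})

test_that("a perfectly separable cohort yields an all-ones ROC-AUC matrix", {
  set.seed(54)
  b <- lapply(stats::setNames(2008:2010, 2008:2010), function(y) {
    n <- 100
    marker <- rbinom(n, 1, 0.3)
    df <- data.frame(outcome = marker, year = y, age = rnorm(n, 60, 10),
                     gender = factor(sample(c("F", "M"), n, TRUE)),
                     ethnicity = factor(sample(c("A", "B"), n, TRUE)))
    df$chapter.Marker <- marker
    df
  })
  sp <- make_splits(b, seed = 6)
  ms <- fit_yearly_models(b, sp, "random_forest", n_trees = 100L,
                          max_depth = 5L, seed = 7)
  ev <- interyear_evaluation(ms, b, sp, metric = "roc_auc")
  expect_equal(unname(ev$M), matrix(1, 3, 3))
})

test_that("majority-class accuracy anchor holds", {
  batches <- make_batches("null", n_per_year = 200, seed = 23)
  b <- batches[[1]]
  prev <- mean(b$outcome)
  acc <- thresholded_metric(rep(0, nrow(b)), b$outcome, threshold = 0.5,
                            metric = "accuracy")
  expect_equal(acc, 1 - prev)
})
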