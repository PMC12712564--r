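# DTH estimation: smoothing arithmetic, Bayes' rule, total probability.

# Two tiny hand-built yearly batches.
two_batches <- function() {
  b1 <- data.frame(outcome = c(0L, 0L, 1L, 1L), x = c("A", "A", "B", "B"))
  b2 <- data.frame(outcome = c(0L, 0L, 0L, 1L), x = c("A", "B", "B", "B"))
  list(`2008` = b1, `2009` = b2)
}

test_that("marginal DTH matches the Laplace formula", {
  b <- two_batches()
  d0 <- marginal_dth(b, "x", alpha = 0)
  expect_equal(unname(d0$P[, "2008"]), c(0.5, 0.5))

  # counts {A:4, B:0}, alpha = 1, |support| = 2 -> (5/6, 1/6)
  b$`2008`$x <- rep("A", 4)
  b$`2009`$x <- c("A", "B", "B", "B")   # keeps B in the union support
  d1 <- marginal_dth(b, "x", alpha = 1)
  expect_equal(unname(d1$P[, "2008"]), c(5 / 6, 1 / 6))
  expect_equal(unname(colSums(d1$P)), c(1, 1))

  expect_error(marginal_dth(list(`2008` = b$`2008`[0, ], `2009` = b$`2009`),
                            "x"),
               class = "empty_batch_error")
})

test_that("numeric variables are binned over the pooled range", {
  b <- list(`2008` = data.frame(age = seq(20, 60, length.out = 50)),
            `2009` = data.frame(age = seq(40, 90, length.out = 50)))
  d <- marginal_dth(b, "age", alpha = 0, bins = 10)
  expect_equal(length(d$support), 10)
  expect_equal(unname(colSums(d$P)), c(1, 1))
})

test_that("prior DTH reports class frequencies with degenerate-year warnings", {
  b <- two_batches()
  p <- prior_dth(b)
  expect_equal(unname(p$P[, "2008"]), c(0.5, 0.5))
  expect_equal(unname(p$P[, "2009"]), c(0.75, 0.25))

  b$`2009`$outcome <- rep(0L, 4)
  p2 <- prior_dth(b)
  expect_match(p2$warnings, "2009")
  expect_equal(unname(p2$P["1", "2009"]), 0)
})

test_that("null-cohort death-rate row is flat up to binomial noise", {
  batches <- make_batches("null", n_per_year = 2000, seed = 13)
  p <- prior_dth(batches)
  death <- p$P["1", ]
  se <- sqrt(0.0291 * (1 - 0.0291) / 2000)
  expect_lte(max(death) - min(death), 6 * se)
})

test_that("conditional DTH equals marginal when feature and outcome are independent", {
  set.seed(21)
  b <- lapply(stats::setNames(2008:2010, 2008:2010), function(y) {
    data.frame(outcome = rbinom(3000, 1, 0.3),
               x = sample(c("A", "B", "C"), 3000, TRUE, c(0.5, 0.3, 0.2)))
  })
  m <- marginal_dth(b, "x", alpha = 0)
  c1 <- conditional_dth(b, "x", 1, alpha = 0)
  tv <- max(colSums(abs(m$P - c1$P)) / 2)
  expect_lt(tv, 0.05)
})

test_that("conditional DTH degenerates to uniform under smoothing when the class is absent", {
  b <- two_batches()
  b$`2009`$outcome <- rep(0L, 4)
  expect_warning(cd <- conditional_dth(b, "x", 1, alpha = 0.5),
                 "absent")
  expect_equal(unname(cd$P[, "2009"]), c(0.5, 0.5))
  expect_error(suppressWarnings(conditional_dth(b, "x", 1, alpha = 0)),
               class = "empty_batch_error")
})

test_that("posterior DTH applies Bayes' rule", {
  # Hand case: p(x=1|y=1)=0.2, p(x=1|y=0)=0.1, p(y=1)=0.0291
  mk <- function(p1) {
    new <- ehrshift:::new_temporal_distribution
    new("x", "conditional", c("0", "1"), 2008L,
        matrix(c(1 - p1, p1), ncol = 1,
               dimnames = list(c("0", "1"), "2008")), 0)
  }
  conds <- list(`0` = mk(0.1), `1` = mk(0.2))
  prior <- ehrshift:::new_temporal_distribution(
    "outcome", "prior", c("0", "1"), 2008L,
    matrix(c(0.9709, 0.0291), ncol = 1,
           dimnames = list(c("0", "1"), "2008")), 0)
  post <- posterior_dth(conds, prior)
  expect_equal(post$P["1", "1", "2008"], 0.0566, tolerance = 1e-4 / 0.0566)
  # Class probabilities sum to 1 per (value, year).
  expect_equal(unname(apply(post$P, c(1, 3), sum)),
               matrix(1, 2, 1), ignore_attr = TRUE)

  # Equal conditionals across classes -> posterior equals the prior.
  conds_eq <- list(`0` = mk(0.2), `1` = mk(0.2))
  post_eq <- posterior_dth(conds_eq, prior)
  expect_equal(unname(post_eq$P["1", , "2008"]), c(0.9709, 0.0291))

  # Mismatched supports are rejected.
  bad <- mk(0.2); bad$support <- c("0", "2")
  expect_error(posterior_dth(list(`0` = mk(0.1), `1` = bad), prior),
               class = "alignment_error")
})

test_that("law of total probability holds exactly at alpha = 0", {
  batches <- make_batches("combined", n_per_year = 300, seed = 5)
  m <- marginal_dth(batches, "chapter.Circulatory", alpha = 0)
  pr <- prior_dth(batches)
  conds <- lapply(stats::setNames(c("0", "1"), c("0", "1")), function(cl) {
    conditional_dth(batches, "chapter.Circulatory", as.integer(cl),
                    alpha = 0)
  })
  recon <- conds$`0`$P * rep(pr$P["0", ], each = 2) +
    conds$`1`$P * rep(pr$P["1", ], each = 2)
  expect_equal(recon, m$P, tolerance = 1e-12)
})

test_that("permuting year order permutes DTH columns identically", {
  batches <- make_batches("covariate", n_per_year = 100, seed = 9)
  d <- marginal_dth(batches, "chapter.Imaging")
  perm <- rev(seq_along(batches))
  d_perm <- marginal_dth(batches[perm], "chapter.Imaging")
  expect_equal(d_perm$P, d$P[, perm])
})

test_that("DTHs round-trip to CSV with a JSON sidecar", {
  batches <- make_batches("null", n_per_year = 60, seed = 6)
  d <- marginal_dth(batches, "chapter.Imaging")
  path <- withr::local_tempfile(fileext = ".csv")
  write_dth(d, path)
  back <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  expect_equal(as.matrix(back), d$P, ignore_attr = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$kind, "marginal")
  expect_equal(side$alpha, 0.5)
})
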