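# Yearly model grid: stratified 56/24/20 train/validation/test splits per
# temporal batch, grid search selecting hyperparameters by mean validation
# ROC-AUC across the yearly models, Youden-index decision thresholds, and
# interyear evaluation matrices.

#' Stratified yearly train/validation/test splits
#'
#' Each year is split 80/20 into training+validation and test; the 80% is
#' split 70/30 into pure training and validation (so 56%/24%/20% of the
#' year overall). Splits are stratified by outcome and fully determined by
#' the seed.
#'
#' @param batches named list of yearly feature tables.
#' @param seed integer seed.
#' @return a `yearly_splits` object: per year, integer row indices
#'   `$train`, `$validation`, `$test` into that year's batch.
#' @export
make_splits <- function(batches, seed = 1L) {
  splits <- lapply(names(batches), function(yr) {
    b <- batches[[yr]]
    if (nrow(b) < 25) {
      abort(sprintf("year %s has fewer than 25 rows", yr), "split_error")
    }
    if (length(unique(b$outcome)) < 2) {
      abort(sprintf("year %s lacks one outcome class", yr), "split_error")
    }
    with_seed(derive_seed(seed, "split", as.integer(yr)), {
      parts <- list(train = integer(), validation = integer(),
                    test = integer())
      for (cl in unique(b$outcome)) {
        idx <- which(b$outcome == cl)
        idx <- idx[sample.int(length(idx))]   # safe for length-1 classes
        n_test <- round(0.2 * length(idx))
        rest <- idx[setdiff(seq_along(idx), seq_len(n_test))]
        n_val <- round(0.3 * length(rest))
        parts$test <- c(parts$test, idx[seq_len(n_test)])
        parts$validation <- c(parts$validation, rest[seq_len(n_val)])
        parts$train <- c(parts$train,
                         rest[setdiff(seq_along(rest), seq_len(n_val))])
      }
      lapply(parts, sort)
    })
  })
  names(splits) <- names(batches)
  structure(splits, class = "yearly_splits")
}

#' Default hyperparameter grids
#'
#' The grids contain the reference configurations (random forest: 500
#' trees, depth 9; gradient boosting: 100 estimators, depth 2) among
#' coarser and finer alternatives.
#'
#' @param algorithm `"random_forest"` or `"gradient_boosting"`.
#' @return a data frame, one row per grid point.
#' @export
default_grid <- function(algorithm = c("random_forest",
                                       "gradient_boosting")) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "random_forest") {
    expand.grid(n_trees = c(100L, 500L), max_depth = c(3L, 9L))
  } else {
    expand.grid(n_trees = c(50L, 100L), max_depth = c(2L, 4L))
  }
}

# Fit one classifier on a feature matrix; returns a predict closure.
fit_classifier <- function(x, y, algorithm, n_trees, max_depth, seed) {
  if (algorithm == "random_forest") {
    fit <- ranger::ranger(
      x = x, y = factor(y, levels = c(0, 1)),
      num.trees = n_trees, max.depth = max_depth, probability = TRUE,
      seed = seed, num.threads = 1L
    )
    function(newx) {
      p <- stats::predict(fit, data = newx, num.threads = 1L)$predictions
      if ("1" %in% colnames(p)) p[, "1"] else rep(0, nrow(p))
    }
  } else {
    dtrain <- xgboost::xgb.DMatrix(data = as.matrix(x), label = y)
    params <- list(objective = "binary:logistic", max_depth = max_depth,
                   eta = 0.3, nthread = 1L, seed = seed)
    fit <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = n_trees, verbose = 0)
    function(newx) {
      stats::predict(fit, xgboost::xgb.DMatrix(data = as.matrix(newx)))
    }
  }
}

#' Grid search by mean same-year validation ROC-AUC
#'
#' For each grid point, one model per year is trained on that year's
#' training rows and scored by ROC-AUC on the same year's validation rows;
#' the grid point with the highest mean across years wins. Ties are broken
#' toward the smaller model (fewer trees, then shallower). A year whose
#' validation set is single-class is excluded from the mean with a warning.
#'
#' @param batches named list of yearly feature tables.
#' @param splits a `yearly_splits`.
#' @param algorithm `"random_forest"` or `"gradient_boosting"`.
#' @param grid data frame with columns `n_trees`, `max_depth`.
#' @param seed integer seed (per-fit seeds derive from seed, year and grid
#'   point so results are independent of evaluation order).
#' @return one-row data frame: the chosen grid point plus its
#'   `mean_val_auc`; the full scored grid is attached as attribute
#'   `"scores"`.
#' @export
select_hyperparameters <- function(batches, splits,
                                   algorithm = c("random_forest",
                                                 "gradient_boosting"),
                                   grid = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  grid <- grid %||% default_grid(algorithm)
  if (nrow(grid) == 0) abort("empty hyperparameter grid",
                             "configuration_error")
  years <- names(batches)
  xs <- lapply(batches, feature_matrix)

  mean_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    aucs <- c()
    for (yr in years) {
      sp <- splits[[yr]]
      val_y <- batches[[yr]]$outcome[sp$validation]
      if (length(unique(val_y)) < 2) {
        warning(sprintf("year %s validation set is single-class; excluded",
                        yr))
        next
      }
      pred <- fit_classifier(
        xs[[yr]][sp$train, , drop = FALSE],
        batches[[yr]]$outcome[sp$train],
        algorithm, grid$n_trees[g], grid$max_depth[g],
        seed = derive_seed(seed, paste0("fit", g), as.integer(yr))
      )
      aucs <- c(aucs, roc_auc(pred(xs[[yr]][sp$validation, , drop = FALSE]),
                              val_y))
    }
    mean_auc[g] <- mean(aucs)
  }
  best <- which(mean_auc == max(mean_auc))
  best <- best[order(grid$n_trees[best], grid$max_depth[best])][1]
  out <- cbind(grid[best, , drop = FALSE], mean_val_auc = mean_auc[best])
  rownames(out) <- NULL
  attr(out, "scores") <- cbind(grid, mean_val_auc = mean_auc)
  out
}

#' Youden-index decision threshold
#'
#' Candidates are the distinct predicted scores; for each candidate c the
#' prediction is positive iff score >= c and J = sensitivity +
#' specificity - 1. Returns the candidate maximizing J (ties: smallest
#' candidate) together with the full candidate record.
#'
#' @param scores predicted probabilities.
#' @param labels binary 0/1 labels (both classes required).
#' @return list with `threshold`, `J`, and `record` (a data frame of
#'   candidate, sensitivity, specificity, J).
#' @export
youden_threshold <- function(scores, labels) {
  if (length(unique(labels)) < 2) {
    abort("Youden threshold requires both classes", "threshold_error")
  }
  cand <- sort(unique(scores))
  # Decision thresholds live strictly inside (0, 1): a cut at 0 (everything
  # positive) or 1 is not a usable operating point.
  cand <- cand[cand > 0 & cand < 1]
  if (length(cand) == 0) {
    warning("no usable threshold candidates; falling back to 0.5")
    cand <- 0.5
  }
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  sens <- vapply(cand, function(c) mean(pos >= c), 0)
  spec <- vapply(cand, function(c) mean(neg < c), 0)
  J <- sens + spec - 1
  best <- which(J == max(J))[1]          # candidates ascending: smallest wins
  list(threshold = cand[best], J = J[best],
       record = data.frame(candidate = cand, sensitivity = sens,
                           specificity = spec, J = J))
}

#' Fit one classifier per yearly batch
#'
#' Each year's model is trained on that year's pure-training rows. Decision
#' thresholds are selected with the Youden index on the most recent year's
#' validation predictions: per model by default, or a single global
#' threshold (from the most recent year's own model) with
#' `threshold_mode = "global"`.
#'
#' @inheritParams select_hyperparameters
#' @param n_trees,max_depth fixed hyperparameters (e.g. from
#'   [select_hyperparameters()]).
#' @param threshold_mode `"per_model"` or `"global"`.
#' @return a `model_set`: per-year predict closures, thresholds,
#'   threshold-selection records and metadata.
#' @export
fit_yearly_models <- function(batches, splits,
                              algorithm = c("random_forest",
                                            "gradient_boosting"),
                              n_trees = 500L, max_depth = 9L, seed = 1L,
                              threshold_mode = c("per_model", "global")) {
  algorithm <- match.arg(algorithm)
  threshold_mode <- match.arg(threshold_mode)
  years <- names(batches)
  xs <- lapply(batches, feature_matrix)

  models <- lapply(years, function(yr) {
    sp <- splits[[yr]]
    fit_classifier(xs[[yr]][sp$train, , drop = FALSE],
                   batches[[yr]]$outcome[sp$train],
                   algorithm, n_trees, max_depth,
                   seed = derive_seed(seed, "model", as.integer(yr)))
  })
  names(models) <- years

  # Threshold selection on the most recent batch's validation data. If that
  # validation set is single-class (possible in very small batches with a
  # rare outcome), fall back to the latest year whose validation set has
  # both classes.
  usable <- vapply(years, function(yr) {
    length(unique(batches[[yr]]$outcome[splits[[yr]]$validation])) == 2
  }, TRUE)
  if (!any(usable)) {
    abort("no year has a two-class validation set", "threshold_error")
  }
  last <- years[max(which(usable))]
  if (last != years[length(years)]) {
    warning(sprintf(
      "most recent year's validation set is single-class; thresholds selected on year %s",
      last))
  }
  sp_last <- splits[[last]]
  val_x <- xs[[last]][sp_last$validation, , drop = FALSE]
  val_y <- batches[[last]]$outcome[sp_last$validation]
  records <- list()
  if (threshold_mode == "global") {
    yt <- youden_threshold(models[[last]](val_x), val_y)
    thresholds <- stats::setNames(rep(yt$threshold, length(years)), years)
    records[[last]] <- yt$record
  } else {
    thresholds <- vapply(years, function(yr) {
      yt <- youden_threshold(models[[yr]](val_x), val_y)
      records[[yr]] <<- yt$record
      yt$threshold
    }, 0)
  }

  structure(list(models = models, algorithm = algorithm,
                 n_trees = n_trees, max_depth = max_depth,
                 thresholds = thresholds, threshold_records = records,
                 threshold_mode = threshold_mode, years = years,
                 threshold_source_year = last, seed = seed),
            class = "model_set")
}

#' Interyear evaluation matrices
#'
#' `M[i, j]` is the metric of the model trained on year i, evaluated on
#' year j's held-out 20% test rows only. Thresholded metrics binarize at
#' the model's Youden threshold; `roc_auc` and `pr_auc` ignore it. A test
#' year with a single class yields NA (undefined) for ranking metrics.
#'
#' @param models a `model_set`.
#' @param batches named list of yearly feature tables.
#' @param splits the `yearly_splits` used to fit the models.
#' @param metric one or more of `roc_auc`, `pr_auc`, `precision`,
#'   `recall`, `accuracy`, `macro_f1`.
#' @return a single `eval_matrix`, or a named list of them when several
#'   metrics are requested (model predictions are computed once).
#' @export
interyear_evaluation <- function(models, batches, splits,
                                 metric = metric_names()) {
  stopifnot(all(metric %in% metric_names()))
  years <- models$years
  xs <- lapply(batches, feature_matrix)
  test_y <- lapply(years, function(yr) {
    batches[[yr]]$outcome[splits[[yr]]$test]
  })
  names(test_y) <- years

  # scores[[i]][[j]]: model i on year j's test rows. One stacked prediction
  # per model, split back by year, keeps the 12 x 12 grid cheap.
  test_x <- do.call(rbind, lapply(years, function(yr) {
    xs[[yr]][splits[[yr]]$test, , drop = FALSE]
  }))
  test_year <- rep(years, vapply(years, function(yr) {
    length(splits[[yr]]$test)
  }, 0L))
  scores <- lapply(years, function(yi) {
    s <- models$models[[yi]](test_x)
    split(s, factor(test_year, levels = years))
  })

  build <- function(m) {
    M <- matrix(NA_real_, length(years), length(years),
                dimnames = list(train = years, test = years))
    for (i in seq_along(years)) {
      for (j in seq_along(years)) {
        M[i, j] <- compute_metric(m, scores[[i]][[j]], test_y[[j]],
                                  models$thresholds[[years[i]]])
      }
    }
    structure(list(metric = m, M = M, labels = years,
                   thresholded = !(m %in% c("roc_auc", "pr_auc")),
                   n_test = vapply(test_y, length, 0L)),
              class = "eval_matrix")
  }
  out <- lapply(metric, build)
  names(out) <- metric
  if (length(out) == 1L) out[[1]] else out
}

#' Write an evaluation matrix as labeled CSV
#'
#' @param em an `eval_matrix`.
#' @param path CSV path.
#' @return invisibly, `path`.
#' @export
write_eval_matrix <- function(em, path) {
  utils::write.csv(as.data.frame(em$M), path, row.names = TRUE)
  invisible(path)
}

#' @export
print.eval_matrix <- function(x, ...) {
  cat(sprintf("<eval_matrix> %s, %d x %d years (%s)\n", x$metric,
              nrow(x$M), ncol(x$M),
              if (x$thresholded) "thresholded" else "threshold-free"))
  invisible(x)
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("<model_set> %s, %d yearly models (trees=%d depth=%d), %s thresholds from year %s\n",
              x$algorithm, length(x$models), x$n_trees, x$max_depth,
              x$threshold_mode, x$threshold_source_year))
  invisible(x)
}
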