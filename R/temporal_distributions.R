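# Data temporal heatmaps (DTHs): per-year estimates of the marginal p(x),
# the class prior p(y), class-conditionals p(x|y) and Bayes posteriors
# p(y|x), stored as value x year probability matrices.

new_temporal_distribution <- function(variable, kind, support, years, P,
                                      alpha, classes = NULL,
                                      warnings = character()) {
  structure(list(variable = variable, kind = kind, support = support,
                 years = years, P = P, alpha = alpha, classes = classes,
                 warnings = warnings),
            class = "temporal_distribution")
}

# Pooled support of a variable across batches; numeric variables with more
# than two distinct values are cut into equal-width bins over the pooled
# range (the bin labels become the support).
variable_values <- function(batches, variable, bins = 20L) {
  all_vals <- unlist(lapply(batches, function(b) b[[variable]]),
                     use.names = FALSE)
  if (is.numeric(all_vals) && length(unique(all_vals)) > 2) {
    breaks <- seq(min(all_vals), max(all_vals), length.out = bins + 1L)
    breaks[1] <- breaks[1] - 1e-9
    vals <- lapply(batches, function(b) {
      as.character(cut(b[[variable]], breaks = breaks, include.lowest = TRUE))
    })
    support <- levels(cut(all_vals, breaks = breaks, include.lowest = TRUE))
  } else {
    vals <- lapply(batches, function(b) as.character(b[[variable]]))
    support <- as.character(sort(unique(all_vals)))
  }
  list(values = vals, support = support)
}

# Shared counting core: Laplace-smoothed per-year frequency columns.
count_columns <- function(values_by_year, support, alpha) {
  P <- sapply(values_by_year, function(v) {
    n <- length(v)
    cnt <- table(factor(v, levels = support))
    (as.numeric(cnt) + alpha) / (n + alpha * length(support))
  })
  rownames(P) <- support
  P
}

#' Marginal distribution heatmap p(x) over years
#'
#' `P[v, t] = (count(v in year t) + alpha) / (n_t + alpha * |support|)`;
#' the support is the union of observed values over all years. Numeric
#' variables are discretized into equal-width bins over the pooled range.
#'
#' @param batches named list of yearly feature tables ([batch_by_year()]).
#' @param variable column name.
#' @param alpha Laplace smoothing parameter (default 0.5, Jeffreys-style,
#'   so no cell is exactly zero before dissimilarity computation).
#' @param bins number of equal-width bins for numeric variables.
#' @return a `temporal_distribution` with kind `"marginal"`.
#' @export
marginal_dth <- function(batches, variable, alpha = 0.5, bins = 20L) {
  if (any(vapply(batches, nrow, 0L) == 0)) {
    abort("empty yearly batch", "empty_batch_error")
  }
  if (!all(vapply(batches, function(b) variable %in% names(b), TRUE))) {
    abort(sprintf("variable '%s' missing from a batch", variable),
          "schema_error")
  }
  vv <- variable_values(batches, variable, bins)
  P <- count_columns(vv$values, vv$support, alpha)
  colnames(P) <- names(batches)
  new_temporal_distribution(variable, "marginal", vv$support,
                            as.integer(names(batches)), P, alpha)
}

#' Class-prior heatmap p(y) over years
#'
#' Unsmoothed class frequencies per year (a 2 x n_years matrix for a binary
#' outcome). A year with a single observed class is emitted with a
#' degenerate column and recorded in `$warnings`.
#'
#' @param batches named list of yearly feature tables.
#' @param alpha smoothing (default 0: plain frequencies).
#' @return a `temporal_distribution` with kind `"prior"`.
#' @export
prior_dth <- function(batches, alpha = 0) {
  support <- as.character(sort(unique(unlist(
    lapply(batches, function(b) b$outcome)))))
  vals <- lapply(batches, function(b) as.character(b$outcome))
  P <- count_columns(vals, support, alpha)
  colnames(P) <- names(batches)
  warn <- character()
  degenerate <- names(batches)[apply(P == 0, 2, any) & alpha == 0]
  if (length(degenerate)) {
    warn <- sprintf("single observed class in year(s): %s",
                    paste(degenerate, collapse = ", "))
  }
  new_temporal_distribution("outcome", "prior", support,
                            as.integer(names(batches)), P, alpha,
                            warnings = warn)
}

#' Class-conditional distribution heatmap p(x | y = c) over years
#'
#' The marginal DTH computed on the class-`class_value` subset of each year,
#' with the support taken from the full (unconditioned) data so conditionals
#' across classes align. An empty class subset in a year yields the uniform
#' column when `alpha > 0` (the smoothing limit) and a recorded warning.
#'
#' @inheritParams marginal_dth
#' @param class_value outcome class to condition on.
#' @return a `temporal_distribution` with kind `"conditional"`.
#' @export
conditional_dth <- function(batches, variable, class_value, alpha = 0.5,
                            bins = 20L) {
  if (any(vapply(batches, nrow, 0L) == 0)) {
    abort("empty yearly batch", "empty_batch_error")
  }
  vv <- variable_values(batches, variable, bins)
  keep <- lapply(seq_along(batches), function(t) {
    vv$values[[t]][batches[[t]]$outcome == class_value]
  })
  warn <- character()
  empty <- vapply(keep, length, 0L) == 0
  if (any(empty)) {
    if (alpha <= 0) {
      abort(sprintf("class %s absent in year(s) %s with alpha = 0",
                    class_value,
                    paste(names(batches)[empty], collapse = ", ")),
            "empty_batch_error")
    }
    warn <- sprintf("class %s absent in year(s): %s (uniform column emitted)",
                    class_value, paste(names(batches)[empty], collapse = ", "))
    warning(warn)
  }
  P <- count_columns(keep, vv$support, alpha)
  colnames(P) <- names(batches)
  new_temporal_distribution(variable, "conditional", vv$support,
                            as.integer(names(batches)), P, alpha,
                            classes = class_value, warnings = warn)
}

#' Posterior distribution heatmap p(y | x) over years via Bayes' rule
#'
#' `P[c | v, t] = p(v | c, t) p(c, t) / sum_c' p(v | c', t) p(c', t)`.
#' Cells with zero denominator are flagged undefined (NA) rather than 0.
#'
#' @param conditionals named list of `temporal_distribution`s of kind
#'   `"conditional"`, one per class, sharing support and years; names are
#'   the class labels.
#' @param prior a `temporal_distribution` of kind `"prior"` over the same
#'   years whose support covers the class labels.
#' @return a `temporal_distribution` of kind `"posterior"` whose `$P` is a
#'   3-d array `[value, class, year]`; for every (value, year) the class
#'   probabilities sum to 1 (where defined).
#' @export
posterior_dth <- function(conditionals, prior) {
  classes <- names(conditionals)
  ref <- conditionals[[1]]
  for (cd in conditionals) {
    if (!identical(cd$support, ref$support) ||
        !identical(cd$years, ref$years)) {
      abort("conditionals must share support and years", "alignment_error")
    }
  }
  if (!identical(prior$years, ref$years)) {
    abort("prior years do not match conditionals", "alignment_error")
  }
  if (!all(classes %in% prior$support)) {
    abort("prior support must cover the conditional class labels",
          "alignment_error")
  }
  nv <- length(ref$support); nc <- length(classes); nt <- length(ref$years)
  post <- array(NA_real_, dim = c(nv, nc, nt),
                dimnames = list(ref$support, classes, ref$years))
  for (t in seq_len(nt)) {
    num <- sapply(classes, function(cl) {
      conditionals[[cl]]$P[, t] * prior$P[cl, t]
    })                                   # nv x nc
    den <- rowSums(num)
    ok <- den > 0
    post[ok, , t] <- num[ok, , drop = FALSE] / den[ok]
  }
  new_temporal_distribution(ref$variable, "posterior", ref$support,
                            ref$years, post, ref$alpha, classes = classes)
}

#' Write / read a DTH as a CSV matrix with a JSON sidecar
#'
#' The CSV holds the probability matrix (rows = support values, columns =
#' years); the sidecar records variable, kind, alpha and classes. Posterior
#' DTHs are flattened to rows `value|class`.
#'
#' @param dth a `temporal_distribution`.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return invisibly, `path`.
#' @export
write_dth <- function(dth, path) {
  P <- dth$P
  if (dth$kind == "posterior") {
    P <- matrix(aperm(P, c(1, 2, 3)), nrow = dim(P)[1] * dim(P)[2],
                dimnames = list(
                  paste(rep(dimnames(dth$P)[[1]], times = dim(P)[2]),
                        rep(dimnames(dth$P)[[2]], each = dim(P)[1]),
                        sep = "|"),
                  dimnames(dth$P)[[3]]))
  }
  utils::write.csv(as.data.frame(P), path, row.names = TRUE)
  jsonlite::write_json(
    list(variable = dth$variable, kind = dth$kind, alpha = dth$alpha,
         classes = dth$classes, years = dth$years, support = dth$support),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.temporal_distribution <- function(x, ...) {
  cat(sprintf("<temporal_distribution> %s p-kind=%s support=%d years=%d alpha=%g\n",
              x$variable, x$kind, length(x$support), length(x$years),
              x$alpha))
  invisible(x)
}
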