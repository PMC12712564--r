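# Association between temporal partitions: hierarchical and k-means
# clustering of IGT embeddings, year-level cross-tabulation, the two-sided
# Fisher exact test and Benjamini-Hochberg FDR control.

new_partition <- function(labels, clusters, method, k, meta = list()) {
  structure(list(years = labels,
                 cluster = stats::setNames(as.integer(clusters), labels),
                 method = method, k = k, meta = meta),
            class = "temporal_partition")
}

#' Hierarchical temporal partition of an IGT embedding
#'
#' Complete-linkage agglomerative clustering on Manhattan distances between
#' embedding coordinates, with the dendrogram cut at k clusters.
#'
#' @param embedding an `igt_projection` (or a coordinate matrix with row
#'   labels).
#' @param k number of clusters (2 <= k < batch count).
#' @return a `temporal_partition`.
#' @export
hierarchical_partition <- function(embedding, k = 2L) {
  coords <- if (inherits(embedding, "igt_projection")) embedding$coords else
    as.matrix(embedding)
  labels <- rownames(coords)
  if (k <= 1) abort("k must be at least 2", "parameter_error")
  if (k >= nrow(coords)) abort("k must be below the batch count",
                               "parameter_error")
  hc <- stats::hclust(stats::dist(coords, method = "manhattan"),
                      method = "complete")
  cl <- stats::cutree(hc, k = k)
  new_partition(labels, cl, "hierarchical", k,
                meta = list(linkage = "complete", distance = "manhattan",
                            hclust = hc))
}

#' k-means temporal partition initialized at the first and last years
#'
#' Lloyd iterations from two fixed initial centroids placed at the first
#' and last years' coordinates, following the natural temporal ordering;
#' deterministic given the embedding.
#'
#' @param embedding an `igt_projection` or coordinate matrix.
#' @param k number of clusters (default and paper convention: 2; the
#'   initial centroids are the first and last batches, so k must be 2).
#' @return a `temporal_partition`.
#' @export
kmeans_partition <- function(embedding, k = 2L) {
  coords <- if (inherits(embedding, "igt_projection")) embedding$coords else
    as.matrix(embedding)
  labels <- rownames(coords)
  if (k != 2L) abort("first/last-year initialization defines k = 2",
                     "parameter_error")
  init <- coords[c(1, nrow(coords)), , drop = FALSE]
  if (max(abs(init[1, ] - init[2, ])) < 1e-12) {
    abort("first and last year coordinates coincide; k-means init degenerate",
          "degenerate_init_error")
  }
  km <- suppressWarnings(
    stats::kmeans(coords, centers = init, iter.max = 100L,
                  algorithm = "Lloyd")
  )
  new_partition(labels, km$cluster, "kmeans", k,
                meta = list(init = "first/last year", centers = km$centers,
                            iter = km$iter))
}

#' Elbow suggestion for the number of temporal clusters
#'
#' Computes the total within-cluster Manhattan dispersion (distances to the
#' componentwise cluster median, which minimizes the Manhattan sum, so the
#' curve is non-increasing over nested hierarchical cuts) for k = 1..k_max
#' and suggests the k maximizing the second difference of the curve.
#'
#' @param embedding an `igt_projection` or coordinate matrix.
#' @param k_max largest k to examine (>= 3, < batch count).
#' @return list with `k` (suggested) and `curve` (data frame k,
#'   dispersion).
#' @export
elbow_k <- function(embedding, k_max = 6L) {
  coords <- if (inherits(embedding, "igt_projection")) embedding$coords else
    as.matrix(embedding)
  if (k_max < 3) abort("k_max must be at least 3", "parameter_error")
  if (k_max >= nrow(coords)) abort("k_max must be below the batch count",
                                   "parameter_error")
  hc <- stats::hclust(stats::dist(coords, method = "manhattan"),
                      method = "complete")
  disp <- vapply(seq_len(k_max), function(k) {
    cl <- stats::cutree(hc, k = k)
    sum(vapply(unique(cl), function(g) {
      x <- coords[cl == g, , drop = FALSE]
      med <- apply(x, 2, stats::median)
      sum(abs(sweep(x, 2, med, "-")))
    }, 0))
  }, 0)
  second_diff <- if (k_max >= 3) diff(diff(disp)) else numeric()
  suggested <- if (length(second_diff)) which.max(second_diff) + 1L else 2L
  list(k = as.integer(suggested),
       curve = data.frame(k = seq_len(k_max), dispersion = disp))
}

#' Cross-tabulate two temporal partitions
#'
#' @param a,b `temporal_partition`s over identical year sets.
#' @return a `contingency_table`: counts of years per (cluster of a,
#'   cluster of b).
#' @export
cross_tab <- function(a, b) {
  if (!setequal(a$years, b$years)) {
    abort("partitions cover different year sets", "alignment_error")
  }
  yrs <- a$years
  tab <- table(a = a$cluster[yrs], b = b$cluster[yrs])
  structure(list(counts = unclass(tab), a_method = a$method,
                 b_method = b$method, years = yrs),
            class = "contingency_table")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Probability-ordering rule: the p-value is the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (ties included). A zero
#' margin yields p = 1 with a warning. Tables larger than 2x2 are rejected
#' explicitly rather than approximated.
#'
#' @param table a `contingency_table` or plain 2x2 count matrix.
#' @return the two-sided p-value.
#' @export
fisher_exact <- function(table) {
  counts <- if (inherits(table, "contingency_table")) table$counts else
    as.matrix(table)
  if (!all(dim(counts) == c(2, 2))) {
    abort("only 2x2 tables are supported (the analysis uses k = 2 clusters)",
          "parameter_error")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be nonnegative integers", "range_error")
  }
  r1 <- sum(counts[1, ]); c1 <- sum(counts[, 1]); n <- sum(counts)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) {
    warning("degenerate contingency table (zero margin); p = 1")
    return(1)
  }
  x <- counts[1, 1]
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(x, c1, n - c1, r1)
  # Tolerance absorbs floating-point noise when ranking equal-probability
  # tables (the same convention stats::fisher.test uses).
  min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `adj(i) = min_{j >= i} p(j) m / j`, clipped at 1 and
#' returned in the original order (delegates to [stats::p.adjust()]).
#'
#' @param pvalues numeric p-values in [0, 1].
#' @return adjusted p-values, elementwise >= the raw values.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", "range_error")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Association between a data-shift partition and performance embeddings
#'
#' For each metric's interyear evaluation matrix: performance
#' dissimilarity, MDS embedding (k = 3), partition into k = 2 clusters by
#' the requested method, cross-tabulation against the data partition, and
#' the two-sided Fisher exact test; finally BH adjustment across metrics.
#'
#' @param data_partition a `temporal_partition` from the data IGT.
#' @param eval_matrices named list of `eval_matrix` objects (one per
#'   metric).
#' @param method `"hierarchical"` or `"kmeans"`.
#' @param dissimilarity_mode passed to [performance_dissimilarity()]; the
#'   mode used is recorded in the result to keep the construction explicit.
#' @return a data frame (class `association_result`): metric, method,
#'   dissimilarity mode, raw and FDR-adjusted p; contingency tables in
#'   attribute `"tables"`.
#' @export
associate <- function(data_partition, eval_matrices,
                      method = c("hierarchical", "kmeans"),
                      dissimilarity_mode = c("average", "profile")) {
  method <- match.arg(method)
  dissimilarity_mode <- match.arg(dissimilarity_mode)
  partition_fun <- if (method == "hierarchical") hierarchical_partition else
    kmeans_partition

  res <- list(); tables <- list()
  for (m in names(eval_matrices)) {
    p <- tryCatch({
      D <- performance_dissimilarity(eval_matrices[[m]],
                                     mode = dissimilarity_mode)
      emb <- mds_embed(D, k = 3L)
      perf_part <- partition_fun(emb, k = 2L)
      tab <- cross_tab(data_partition, perf_part)
      tables[[m]] <- tab
      fisher_exact(tab)
    }, ehrshift_error = function(e) {
      abort(sprintf("metric '%s': %s", m, conditionMessage(e)),
            class(e)[1])
    })
    res[[m]] <- data.frame(metric = m, method = method,
                           dissimilarity_mode = dissimilarity_mode,
                           p_raw = p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$p_adjusted <- fdr_adjust(out$p_raw)
  rownames(out) <- NULL
  attr(out, "tables") <- tables
  class(out) <- c("association_result", "data.frame")
  out
}

#' @export
print.temporal_partition <- function(x, ...) {
  cat(sprintf("<temporal_partition> %s, k=%d\n", x$method, x$k))
  print(x$cluster)
  invisible(x)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s x %s over %d years\n",
              x$a_method, x$b_method, length(x$years)))
  print(x$counts)
  invisible(x)
}
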