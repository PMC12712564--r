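# Information-geometric temporal (IGT) projection: dissimilarity matrices
# between per-year distributions, embedded with classical multidimensional
# scaling so batch-to-batch distances reflect distributional dissimilarity.

# Pairwise square-root Jensen-Shannon divergence (base 2) between the
# columns of a probability matrix. Bounded in [0, 1], symmetric, a metric.
js_distance_matrix <- function(P) {
  nt <- ncol(P)
  H <- apply(P, 2, entropy_bits)
  D <- matrix(0, nt, nt, dimnames = list(colnames(P), colnames(P)))
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      m <- (P[, i] + P[, j]) / 2
      js <- entropy_bits(m) - (H[i] + H[j]) / 2
      D[i, j] <- D[j, i] <- sqrt(max(js, 0))
    }
  }
  D
}

#' Jensen-Shannon dissimilarity matrix between yearly distributions
#'
#' `D[i, j]` is the square root of the Jensen-Shannon divergence (base 2)
#' between the year-i and year-j probability vectors; `0 log 0` is treated
#' as 0. Entries lie in [0, 1] and satisfy the metric axioms.
#'
#' @param P a `temporal_distribution`, a `density_map`, or a plain matrix
#'   whose columns are per-year probability vectors summing to 1.
#' @return a `dissimilarity_matrix` (square, symmetric, zero diagonal)
#'   with year labels.
#' @export
js_dissimilarity <- function(P) {
  if (inherits(P, "temporal_distribution")) {
    if (P$kind == "posterior") {
      abort("posterior DTHs are not columnwise distributions; use the combined conditional map instead",
            "normalization_error")
    }
    M <- P$P
  } else if (inherits(P, "density_map")) {
    M <- P$mass
  } else {
    M <- as.matrix(P)
  }
  check_columns_normalized(M, tol = 1e-6, what = "per-year distribution")
  D <- js_distance_matrix(M)
  structure(list(labels = colnames(M), D = D, metric = "sqrt-JS (base 2)"),
            class = "dissimilarity_matrix")
}

#' Classical multidimensional scaling embedding of a dissimilarity matrix
#'
#' Torgerson scaling: double-centered squared dissimilarities, top-k
#' spectral coordinates, axes ordered by eigenvalue. Negative eigenvalues
#' are truncated at zero and the discarded mass is reported as a
#' diagnostic. Axis signs are fixed so the first batch has nonnegative
#' coordinates.
#'
#' @param D a `dissimilarity_matrix` (or plain square symmetric matrix).
#' @param k embedding dimension, 2 or 3 (must be < batch count).
#' @return an `igt_projection`: `coords` (batches x k), `eigenvalues`,
#'   `negative_mass` diagnostic, `labels`.
#' @export
mds_embed <- function(D, k = 2L) {
  labels <- if (inherits(D, "dissimilarity_matrix")) D$labels else
    rownames(D) %||% as.character(seq_len(nrow(as.matrix(D))))
  M <- if (inherits(D, "dissimilarity_matrix")) D$D else as.matrix(D)
  n <- nrow(M)
  if (k >= n) abort("embedding dimension must be below the batch count",
                    "dimension_error")
  # cmdscale warns when fewer than k eigenvalues are positive; the missing
  # axes are padded with zeros below and the eigenvalues stay inspectable.
  fit <- suppressWarnings(stats::cmdscale(M, k = k, eig = TRUE))
  coords <- matrix(0, nrow = n, ncol = k,
                   dimnames = list(labels, paste0("dim", seq_len(k))))
  if (!is.null(fit$points) && ncol(fit$points) > 0) {
    coords[, seq_len(ncol(fit$points))] <- fit$points
  }
  # Sign convention: first batch nonnegative on every axis (first nonzero
  # batch decides when the first is exactly zero).
  for (j in seq_len(k)) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  eig <- fit$eig
  neg_mass <- sum(abs(eig[eig < 0])) / max(sum(abs(eig)), .Machine$double.eps)
  structure(list(labels = labels, coords = coords, eigenvalues = eig,
                 negative_mass = neg_mass, k = k),
            class = "igt_projection")
}

#' Dissimilarity between years from an interyear evaluation matrix
#'
#' Default mode `"average"`: `D[i, j] = 1 - (M[i, j] + M[j, i]) / 2` for
#' i != j with a forced zero diagonal — years whose models transfer well
#' onto each other are close. Mode `"profile"`: Manhattan distance between
#' the concatenated row + column performance profiles of each year,
#' normalized by profile length, as an alternative that uses a year's full
#' evaluation pattern.
#'
#' @param M an `eval_matrix` or plain square matrix with values in [0, 1]
#'   over identical train/test year labels.
#' @param mode `"average"` or `"profile"`.
#' @return a `dissimilarity_matrix`.
#' @export
performance_dissimilarity <- function(M, mode = c("average", "profile")) {
  mode <- match.arg(mode)
  metric_name <- if (inherits(M, "eval_matrix")) M$metric else "metric"
  A <- if (inherits(M, "eval_matrix")) M$M else as.matrix(M)
  if (nrow(A) != ncol(A)) abort("evaluation matrix must be square",
                                "range_error")
  if (anyNA(A)) abort("evaluation matrix contains undefined cells",
                      "range_error")
  if (any(A < 0 | A > 1)) {
    abort("metric values must lie in [0, 1]; normalize before embedding",
          "range_error")
  }
  labels <- rownames(A) %||% as.character(seq_len(nrow(A)))
  if (mode == "average") {
    D <- 1 - (A + t(A)) / 2
    diag(D) <- 0
  } else {
    prof <- cbind(A, t(A))            # row i: train-on-i and test-on-i profiles
    D <- as.matrix(stats::dist(prof, method = "manhattan")) / ncol(prof)
  }
  dimnames(D) <- list(labels, labels)
  structure(list(labels = labels, D = D,
                 metric = sprintf("performance (%s, %s)", metric_name, mode)),
            class = "dissimilarity_matrix")
}

#' Write a dissimilarity matrix or IGT projection to CSV
#'
#' @param x a `dissimilarity_matrix` or `igt_projection`.
#' @param path CSV path.
#' @return invisibly, `path`.
#' @export
write_igt <- function(x, path) {
  if (inherits(x, "dissimilarity_matrix")) {
    utils::write.csv(as.data.frame(x$D), path, row.names = TRUE)
  } else {
    df <- data.frame(batch = x$labels, x$coords, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Scatter plot of an IGT projection with a year-gradient color ramp
#'
#' @param x an `igt_projection`.
#' @param dims which two dimensions to draw.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot_igt <- function(x, dims = c(1, 2), ...) {
  cols <- grDevices::hcl.colors(length(x$labels), "Zissou 1")
  graphics::plot(x$coords[, dims[1]], x$coords[, dims[2]], col = cols,
                 pch = 19, xlab = paste0("dim", dims[1]),
                 ylab = paste0("dim", dims[2]), ...)
  graphics::text(x$coords[, dims[1]], x$coords[, dims[2]],
                 labels = x$labels, pos = 3, cex = 0.7)
  invisible(x)
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("<dissimilarity_matrix> %d batches, metric: %s\n",
              length(x$labels), x$metric))
  invisible(x)
}

#' @export
print.igt_projection <- function(x, ...) {
  cat(sprintf("<igt_projection> %d batches in %d dims (negative-eigenvalue mass %.3g)\n",
              length(x$labels), x$k, x$negative_mass))
  invisible(x)
}
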