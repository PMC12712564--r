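# Heatmap-style plots for DTHs and interyear evaluation matrices.

#' Heatmap of a data temporal heatmap (DTH)
#'
#' Rows are support values, columns are years. Posterior DTHs can be drawn
#' with a square-root transformation for visibility of rare-class
#' probabilities; stored values are never transformed.
#'
#' @param dth a `temporal_distribution`.
#' @param sqrt_transform apply sqrt for display (posterior convention).
#' @param ... passed to [graphics::image()].
#' @return invisibly, `dth`.
#' @export
plot_dth <- function(dth, sqrt_transform = FALSE, ...) {
  P <- dth$P
  if (dth$kind == "posterior") {
    # Flatten value x class rows for display.
    P <- matrix(P, nrow = dim(P)[1] * dim(P)[2], dimnames = list(
      paste(rep(dimnames(dth$P)[[1]], times = dim(dth$P)[2]),
            rep(dimnames(dth$P)[[2]], each = dim(dth$P)[1]), sep = "|"),
      dimnames(dth$P)[[3]]))
  }
  Z <- if (sqrt_transform) sqrt(P) else P
  graphics::image(x = seq_along(dth$years), y = seq_len(nrow(Z)), z = t(Z),
                  xlab = "year", ylab = dth$variable, axes = FALSE,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  graphics::axis(1, at = seq_along(dth$years), labels = dth$years)
  graphics::axis(2, at = seq_len(nrow(Z)), labels = rownames(Z), las = 2,
                 cex.axis = 0.6)
  invisible(dth)
}

#' Heatmap of an interyear evaluation matrix
#'
#' @param em an `eval_matrix`.
#' @param ... passed to [graphics::image()].
#' @return invisibly, `em`.
#' @export
plot_eval_matrix <- function(em, ...) {
  n <- nrow(em$M)
  graphics::image(x = seq_len(n), y = seq_len(n), z = t(em$M[n:1, ]),
                  xlab = "test year", ylab = "train year", axes = FALSE,
                  main = em$metric,
                  col = grDevices::hcl.colors(64, "Viridis"), ...)
  graphics::axis(1, at = seq_len(n), labels = em$labels, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(em$labels), las = 2,
                 cex.axis = 0.7)
  invisible(em)
}
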