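# Latent-space density characterization: factorial analysis of mixed data
# (FAMD) to a low-dimensional space, per-year Gaussian kernel density maps
# on a shared grid, and combination/renormalization of class-conditional
# maps.

#' Fit a factorial analysis of mixed data (FAMD) reduction
#'
#' Numeric columns are standardized to unit variance; categorical columns
#' are expanded to indicator columns scaled by the inverse square root of
#' the category proportion and centered; the combined matrix is decomposed
#' by SVD. Binary 0/1 integer columns (the chapter indicators) are treated
#' as two-level categoricals, which is the FAMD convention for one-hot
#' data. Component signs are fixed so each component's largest-magnitude
#' loading is positive.
#'
#' @param features a `feature_table` (or any data frame); `admission_id`,
#'   `year` and `outcome` are excluded from the decomposition but carried
#'   through as metadata.
#' @param d number of latent dimensions to keep (default 3).
#' @return a `latent_coordinates` object: `scores` (n x d), `evr`
#'   (explained-variance ratios for the kept dimensions), `loadings`,
#'   `meta` (year/outcome per row) and the fitted scaling parameters for
#'   out-of-sample projection.
#' @export
fit_mixed_reduction <- function(features, d = 3L) {
  meta_cols <- intersect(c("admission_id", "year", "outcome"),
                         names(features))
  X <- features[, setdiff(names(features), meta_cols), drop = FALSE]
  if (nrow(X) < d + 1) abort("need at least d + 1 rows", "rank_error")

  is_numeric <- vapply(X, function(col) {
    is.numeric(col) && length(unique(col)) > 2
  }, TRUE)

  blocks <- list(); spec <- list()
  for (nm in names(X)) {
    col <- X[[nm]]
    if (is_numeric[[nm]]) {
      # Population sd, so duplicating every row leaves the fit invariant.
      s <- stats::sd(col) * sqrt((length(col) - 1) / length(col))
      if (s == 0 || is.na(s)) {
        warning(sprintf("dropping constant column '%s'", nm))
        next
      }
      z <- (col - mean(col)) / s
      blocks[[nm]] <- matrix(z, dimnames = list(NULL, nm))
      spec[[nm]] <- list(type = "numeric", mean = mean(col), sd = s)
    } else {
      f <- factor(col)
      if (nlevels(f) < 2) {
        warning(sprintf("dropping constant column '%s'", nm))
        next
      }
      ind <- outer(as.character(f), levels(f), "==") * 1
      p <- colMeans(ind)
      Z <- sweep(ind, 2, sqrt(p), "/")
      ctr <- colMeans(Z)
      Z <- sweep(Z, 2, ctr, "-")
      colnames(Z) <- paste0(nm, ".", make.names(levels(f)))
      blocks[[nm]] <- Z
      spec[[nm]] <- list(type = "categorical", levels = levels(f), prop = p,
                         center = ctr)
    }
  }
  Z <- do.call(cbind, blocks)
  sv <- svd(Z)
  pos <- sv$d > max(sv$d) * 1e-10
  if (d > sum(pos)) abort(sprintf("d = %d exceeds rank %d", d, sum(pos)),
                          "rank_error")
  evr_all <- sv$d^2 / sum(sv$d^2)

  V <- sv$v[, seq_len(d), drop = FALSE]
  # Sign convention: largest-magnitude loading positive per component.
  flip <- vapply(seq_len(d), function(k) {
    sign(V[which.max(abs(V[, k])), k])
  }, 0)
  V <- sweep(V, 2, flip, "*")
  scores <- Z %*% V
  colnames(scores) <- paste0("dim", seq_len(d))
  rownames(V) <- colnames(Z)
  colnames(V) <- colnames(scores)

  structure(list(
    scores = scores,
    evr = evr_all[seq_len(d)],
    evr_all = evr_all,
    loadings = V,
    meta = features[, intersect(c("year", "outcome"), names(features)),
                    drop = FALSE],
    spec = spec
  ), class = "latent_coordinates")
}

#' Project new rows through a fitted mixed reduction
#'
#' Applies the stored scaling parameters (means/sds, category proportions
#' and centers) and loadings; projecting the training rows reproduces the
#' fitted scores.
#'
#' @param fit a `latent_coordinates` object.
#' @param newdata data frame with the fitted columns.
#' @return an n x d score matrix.
#' @export
project_mixed_reduction <- function(fit, newdata) {
  blocks <- list()
  for (nm in names(fit$spec)) {
    sp <- fit$spec[[nm]]
    col <- newdata[[nm]]
    if (is.null(col)) abort(sprintf("column '%s' missing", nm),
                            "schema_error")
    if (sp$type == "numeric") {
      blocks[[nm]] <- matrix((col - sp$mean) / sp$sd)
    } else {
      ind <- outer(as.character(col), sp$levels, "==") * 1
      Z <- sweep(ind, 2, sqrt(sp$prop), "/")
      blocks[[nm]] <- sweep(Z, 2, sp$center, "-")
    }
  }
  Z <- do.call(cbind, blocks)
  scores <- Z %*% fit$loadings
  colnames(scores) <- colnames(fit$loadings)
  scores
}

# Normalized Gaussian product-kernel masses on a tensor grid. The product
# kernel is contracted Khatri-Rao style: per-dimension grid x n kernel
# matrices are folded pairwise and the last dimension enters through one
# matrix product, so the full grid x n matrix is never formed. Cells vary
# fastest in dimension 1, matching expand.grid over the axes.
grid_kde_mass <- function(x, axes, h) {
  d <- length(axes)
  K <- lapply(seq_len(d), function(j) {
    outer(axes[[j]], x[, j], function(g, xi) {
      stats::dnorm((g - xi) / h[j]) / h[j]
    })
  })
  sizes <- vapply(axes, length, 0L)
  if (d == 1) {
    dens <- rowSums(K[[1]])
  } else {
    f <- K[[1]]
    if (d == 3) {
      idx1 <- rep(seq_len(sizes[1]), times = sizes[2])
      idx2 <- rep(seq_len(sizes[2]), each = sizes[1])
      f <- f[idx1, , drop = FALSE] * K[[2]][idx2, , drop = FALSE]
    }
    dens <- as.vector(f %*% t(K[[d]]))
  }
  dens / sum(dens)
}

# Scott's rule bandwidth per dimension for an n x d coordinate block.
scott_bandwidth <- function(x) {
  n <- nrow(x); d <- ncol(x)
  h <- apply(x, 2, stats::sd) * n^(-1 / (d + 4))
  pmax(h, 1e-8)
}

#' Per-year kernel density maps on a shared latent grid
#'
#' Evaluates a Gaussian product-kernel density for each year on a common
#' grid spanning the pooled coordinate range (plus a 5% margin), then
#' normalizes each year's grid masses to sum to one. Bandwidths follow
#' Scott's rule per dimension per year and are recorded in the result.
#'
#' @param coords a `latent_coordinates` object or a numeric matrix (n x d,
#'   d <= 3).
#' @param years per-row year labels (defaults to `coords$meta$year`).
#' @param grid_size grid points per dimension; default 32 for d <= 2,
#'   16 for d = 3 (bounds the grid at 4096 cells).
#' @return a `density_map`: `grid` (cell coordinates), `mass` (cells x
#'   years, columns summing to 1), `bandwidths`, `axes`.
#' @export
kde_density_map <- function(coords, years = NULL, grid_size = NULL) {
  if (inherits(coords, "latent_coordinates")) {
    years <- years %||% coords$meta$year
    coords <- coords$scores
  }
  coords <- as.matrix(coords)
  d <- ncol(coords)
  if (d > 3) abort("kernel density maps support at most 3 dimensions",
                   "dimension_error")
  grid_size <- grid_size %||% if (d <= 2) 32L else 16L
  tab <- table(years)
  if (any(tab < 2)) {
    abort(sprintf("year(s) with < 2 points: %s",
                  paste(names(tab)[tab < 2], collapse = ", ")),
          "degenerate_year_error")
  }

  rng <- apply(coords, 2, range)
  margin <- 0.05 * (rng[2, ] - rng[1, ])
  axes <- lapply(seq_len(d), function(j) {
    seq(rng[1, j] - margin[j], rng[2, j] + margin[j],
        length.out = grid_size)
  })
  yl <- sort(unique(years))
  n_cells <- grid_size^d
  mass <- matrix(0, nrow = n_cells, ncol = length(yl),
                 dimnames = list(NULL, yl))
  bw <- matrix(0, nrow = length(yl), ncol = d,
               dimnames = list(yl, paste0("dim", seq_len(d))))

  for (t in seq_along(yl)) {
    x <- coords[years == yl[t], , drop = FALSE]
    h <- scott_bandwidth(x)
    bw[t, ] <- h
    mass[, t] <- grid_kde_mass(x, axes, h)
  }

  grid <- as.matrix(do.call(expand.grid, axes))
  colnames(grid) <- paste0("dim", seq_len(d))
  structure(list(grid = grid, mass = mass, bandwidths = bw, axes = axes,
                 years = as.integer(yl)),
            class = "density_map")
}

#' Combine class-conditional density maps into one renormalized map
#'
#' Per year, the combined mass is the prior-weighted mixture of the class
#' maps, renormalized to sum to one.
#'
#' @param maps named list of `density_map`s, one per class, sharing grids
#'   and years.
#' @param class_weights classes x years weight matrix (e.g. the `$P` of a
#'   prior DTH), rows named by class.
#' @return a `density_map`.
#' @export
combine_conditional_maps <- function(maps, class_weights) {
  ref <- maps[[1]]
  for (m in maps) {
    if (!isTRUE(all.equal(m$grid, ref$grid)) ||
        !identical(m$years, ref$years)) {
      abort("density maps must share grid and years", "alignment_error")
    }
  }
  classes <- names(maps)
  mass <- matrix(0, nrow = nrow(ref$mass), ncol = ncol(ref$mass),
                 dimnames = dimnames(ref$mass))
  for (t in seq_along(ref$years)) {
    w <- class_weights[classes, t]
    mix <- rowSums(sapply(classes, function(cl) w[cl] * maps[[cl]]$mass[, t]))
    mass[, t] <- as.vector(mix) / sum(mix)
  }
  structure(list(grid = ref$grid, mass = mass,
                 bandwidths = lapply(maps, `[[`, "bandwidths"),
                 axes = ref$axes, years = ref$years),
            class = "density_map")
}

#' @export
print.latent_coordinates <- function(x, ...) {
  cat(sprintf("<latent_coordinates> n=%d d=%d evr=%s (%.2f%% total)\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.3f", x$evr), collapse = ", "),
              100 * sum(x$evr)))
  invisible(x)
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d cells x %d years (d=%d)\n",
              nrow(x$mass), ncol(x$mass), ncol(x$grid)))
  invisible(x)
}
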