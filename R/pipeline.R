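# End-to-end orchestration: simulate or ingest, characterize temporal
# shifts, train yearly models, and test the association between data-shift
# and performance partitions — from one configuration, with per-stage seeds
# derived from a single master seed and a manifest recording every
# artifact.

#' Build a run configuration
#'
#' @param scenario a `shift_scenario` (synthetic input), or NULL to read
#'   files.
#' @param admissions_path,codes_path CSV inputs when `scenario` is NULL.
#' @param map_path code-map CSV; NULL uses the packaged synthetic map.
#' @param unmapped_policy passed to [harmonize_codes()].
#' @param reduction_dims latent dimensions for the mixed reduction
#'   (default 3).
#' @param grid_size KDE grid points per dimension (NULL = default rule).
#' @param algorithm classifier family.
#' @param grid_search if TRUE, select hyperparameters by grid search;
#'   otherwise use `n_trees`/`max_depth` as given.
#' @param n_trees,max_depth fixed hyperparameters when `grid_search` is
#'   FALSE (defaults are the reference random-forest configuration).
#' @param metrics evaluation metrics for the interyear matrices.
#' @param method clustering method(s) for the association stage.
#' @param k number of temporal clusters for the data partition.
#' @param seed master seed.
#' @param outdir output directory.
#' @return a `run_config` list (serializable with [write_config()]).
#' @export
run_config <- function(scenario = NULL, admissions_path = NULL,
                       codes_path = NULL, map_path = NULL,
                       unmapped_policy = "error", reduction_dims = 3L,
                       grid_size = NULL,
                       algorithm = "random_forest", grid_search = FALSE,
                       n_trees = 500L, max_depth = 9L,
                       metrics = metric_names(),
                       method = "hierarchical", k = 2L, seed = 1L,
                       outdir = tempfile("ehrshift_run_")) {
  structure(list(scenario = scenario, admissions_path = admissions_path,
                 codes_path = codes_path, map_path = map_path,
                 unmapped_policy = unmapped_policy,
                 reduction_dims = as.integer(reduction_dims),
                 grid_size = grid_size, algorithm = algorithm,
                 grid_search = grid_search, n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth), metrics = metrics,
                 method = method, k = as.integer(k),
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' Round-trips: `read_config(write_config(cfg, path))` reproduces the
#' configuration.
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `write_config`: invisibly, `path`; `read_config`: a
#'   `run_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$scenario)) {
    sc <- unclass(x$scenario)
    # Named numeric vectors become YAML maps (as.list keeps the names).
    for (p in c("chapter_rates_pre", "chapter_rates_post")) {
      sc[[p]] <- as.list(sc[[p]])
    }
    for (p in c("concept_coef_pre", "concept_coef_post")) {
      sc[[p]]$coef <- as.list(sc[[p]]$coef)
    }
    for (p in c("gender_probs", "ethnicity_probs")) {
      sc$demographics[[p]] <- as.list(sc$demographics[[p]])
    }
    x$scenario <- sc
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$scenario)) {
    sc <- x$scenario
    sc$chapter_rates_pre <- unlist(sc$chapter_rates_pre)
    sc$chapter_rates_post <- unlist(sc$chapter_rates_post)
    sc$prevalence_by_year <- unlist(sc$prevalence_by_year)
    sc$changepoint_year <- sc$changepoint_year %||% NA_integer_
    for (p in c("concept_coef_pre", "concept_coef_post")) {
      sc[[p]]$coef <- unlist(sc[[p]]$coef)
    }
    for (p in c("gender_probs", "ethnicity_probs")) {
      sc$demographics[[p]] <- unlist(sc$demographics[[p]])
    }
    class(sc) <- "shift_scenario"
    x$scenario <- validate_scenario(sc)
  }
  do.call(run_config, x)
}

#' Run the full study pipeline
#'
#' Executes the four phases in order — (A) simulate or ingest and
#' harmonize, (B) characterize temporal shifts (DTHs, mixed reduction,
#' per-year density maps, IGT projections, data partition), (C) train
#' yearly models and build interyear evaluation matrices, (D) associate
#' data-shift and performance partitions — writing every intermediate
#' artifact under `config$outdir` and a manifest with artifact hashes and
#' the seed chain. A stage failure aborts with the stage name after
#' writing the partial manifest.
#'
#' @param config a `run_config`.
#' @return the run manifest (list), invisibly including the in-memory
#'   `association` results and `data_partition`.
#' @export
run_study <- function(config) {
  cfg <- config
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, stages = list(), artifacts = list())
  add_artifact <- function(name, path) {
    manifest$artifacts[[name]] <<- list(path = path, md5 = file_md5(path))
  }
  fail <- function(stage, e) {
    manifest$stages[[stage]] <<- list(status = "error",
                                      message = conditionMessage(e))
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
          "stage_error")
  }

  # Stage A: ingest -------------------------------------------------------
  stageA <- tryCatch({
    if (!is.null(cfg$scenario)) {
      cohort <- generate_cohort(cfg$scenario)
      paths <- write_cohort(cohort, file.path(cfg$outdir, "cohort"))
      for (nm in names(paths)) add_artifact(paste0("cohort_", nm), paths[[nm]])
    } else {
      cohort <- read_admissions(cfg$admissions_path, cfg$codes_path)
    }
    map <- if (is.null(cfg$map_path)) example_code_map() else
      load_code_map(cfg$map_path)
    features <- harmonize_codes(cohort, map, cfg$unmapped_policy)
    batches <- batch_by_year(features)
    list(features = features, batches = batches, n = nrow(features))
  }, error = function(e) fail("ingest", e))
  manifest$stages$ingest <- list(status = "ok", rows = stageA$n,
                                 years = length(stageA$batches))
  batches <- stageA$batches

  # Stage B: shift characterization ---------------------------------------
  stageB <- tryCatch({
    dth_dir <- file.path(cfg$outdir, "dth")
    dir.create(dth_dir, showWarnings = FALSE)
    prior <- prior_dth(batches)
    write_dth(prior, file.path(dth_dir, "prior.csv"))
    add_artifact("dth_prior", file.path(dth_dir, "prior.csv"))
    chapter_cols <- grep("^chapter\\.", names(stageA$features), value = TRUE)
    for (v in chapter_cols) {
      p <- file.path(dth_dir, paste0(v, ".csv"))
      write_dth(marginal_dth(batches, v), p)
    }

    famd <- fit_mixed_reduction(stageA$features, d = cfg$reduction_dims)
    kde_full <- kde_density_map(famd, grid_size = cfg$grid_size)
    classes <- sort(unique(stageA$features$outcome))
    kde_class <- lapply(classes, function(cl) {
      keep <- famd$meta$outcome == cl
      kde_on_grid(famd$scores[keep, , drop = FALSE],
                  famd$meta$year[keep], kde_full)
    })
    names(kde_class) <- classes
    combined <- combine_conditional_maps(kde_class, prior$P)

    igt_dir <- file.path(cfg$outdir, "igt")
    dir.create(igt_dir, showWarnings = FALSE)
    igt_data <- mds_embed(js_dissimilarity(kde_full), k = 3L)
    igt_cond <- mds_embed(js_dissimilarity(combined), k = 3L)
    write_igt(igt_data, file.path(igt_dir, "igt_data.csv"))
    write_igt(igt_cond, file.path(igt_dir, "igt_conditional.csv"))
    add_artifact("igt_data", file.path(igt_dir, "igt_data.csv"))
    add_artifact("igt_conditional", file.path(igt_dir, "igt_conditional.csv"))

    data_partition <- hierarchical_partition(igt_data, k = cfg$k)
    jsonlite::write_json(
      list(method = data_partition$method, k = data_partition$k,
           cluster = as.list(data_partition$cluster)),
      file.path(igt_dir, "data_partition.json"), auto_unbox = TRUE)
    add_artifact("data_partition", file.path(igt_dir, "data_partition.json"))
    list(famd = famd, prior = prior, igt_data = igt_data,
         igt_conditional = igt_cond, data_partition = data_partition)
  }, error = function(e) fail("characterize", e))
  manifest$stages$characterize <- list(
    status = "ok",
    evr = stageB$famd$evr,
    variance_3d_pct = 100 * sum(stageB$famd$evr))

  # Stage C: models --------------------------------------------------------
  stageC <- tryCatch({
    split_seed <- derive_seed(cfg$seed, "splits")
    model_seed <- derive_seed(cfg$seed, "models")
    splits <- make_splits(batches, seed = split_seed)
    if (isTRUE(cfg$grid_search)) {
      sel <- select_hyperparameters(batches, splits, cfg$algorithm,
                                    seed = derive_seed(cfg$seed, "grid"))
      n_trees <- sel$n_trees; max_depth <- sel$max_depth
    } else {
      sel <- NULL; n_trees <- cfg$n_trees; max_depth <- cfg$max_depth
    }
    models <- fit_yearly_models(batches, splits, cfg$algorithm,
                                n_trees = n_trees, max_depth = max_depth,
                                seed = model_seed)
    evals <- interyear_evaluation(models, batches, splits,
                                  metric = cfg$metrics)
    if (inherits(evals, "eval_matrix")) {
      evals <- stats::setNames(list(evals), evals$metric)
    }
    mdir <- file.path(cfg$outdir, "models")
    dir.create(mdir, showWarnings = FALSE)
    for (m in names(evals)) {
      p <- file.path(mdir, paste0("eval_", m, ".csv"))
      write_eval_matrix(evals[[m]], p)
      add_artifact(paste0("eval_", m), p)
    }
    jsonlite::write_json(
      list(algorithm = models$algorithm, n_trees = models$n_trees,
           max_depth = models$max_depth,
           thresholds = as.list(models$thresholds),
           threshold_mode = models$threshold_mode,
           grid_selection = if (is.null(sel)) NULL else as.list(sel),
           seeds = list(splits = split_seed, models = model_seed)),
      file.path(mdir, "model_set.json"), auto_unbox = TRUE, digits = NA)
    add_artifact("model_set", file.path(mdir, "model_set.json"))
    list(splits = splits, models = models, evals = evals)
  }, error = function(e) fail("models", e))
  manifest$stages$models <- list(status = "ok",
                                 algorithm = stageC$models$algorithm,
                                 n_trees = stageC$models$n_trees,
                                 max_depth = stageC$models$max_depth)

  # Stage D: association ---------------------------------------------------
  stageD <- tryCatch({
    out <- list()
    for (method in cfg$method) {
      out[[method]] <- associate(stageB$data_partition, stageC$evals,
                                 method = method)
    }
    assoc <- do.call(rbind, out)
    rownames(assoc) <- NULL
    p <- file.path(cfg$outdir, "association.csv")
    utils::write.csv(assoc, p, row.names = FALSE)
    add_artifact("association", p)
    assoc
  }, error = function(e) fail("associate", e))
  manifest$stages$associate <- list(status = "ok",
                                    n_tests = nrow(stageD))

  manifest_path <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(manifest, list(
    association = stageD,
    data_partition = stageB$data_partition,
    igt_data = stageB$igt_data,
    evals = stageC$evals,
    famd = stageB$famd,
    outdir = cfg$outdir
  )))
}

# Evaluate a KDE for new points on an existing map's grid (shared axes), so
# class-conditional maps align with the full map.
kde_on_grid <- function(coords, years, ref_map) {
  coords <- as.matrix(coords)
  d <- ncol(coords)
  axes <- ref_map$axes
  yl <- sort(unique(years))
  mass <- matrix(0, nrow = nrow(ref_map$mass), ncol = length(yl),
                 dimnames = list(NULL, yl))
  bw <- matrix(0, nrow = length(yl), ncol = d,
               dimnames = list(yl, paste0("dim", seq_len(d))))
  ref_bw <- ref_map$bandwidths
  for (t in seq_along(yl)) {
    x <- coords[years == yl[t], , drop = FALSE]
    if (nrow(x) == 0) {
      # No class members this year (rare outcome, small batch): fall back
      # to a uniform column rather than an undefined density.
      warning(sprintf("year %s has no points; uniform mass emitted", yl[t]))
      mass[, t] <- 1 / nrow(mass)
      next
    }
    h <- if (nrow(x) >= 2) scott_bandwidth(x) else
      # Single point: smooth with the reference map's bandwidth for the
      # same year (its full-population spread).
      if (is.matrix(ref_bw) && as.character(yl[t]) %in% rownames(ref_bw)) {
        ref_bw[as.character(yl[t]), ]
      } else {
        vapply(axes, function(a) diff(range(a)) / 10, 0)
      }
    bw[t, ] <- h
    mass[, t] <- grid_kde_mass(x, axes, h)
  }
  structure(list(grid = ref_map$grid, mass = mass, bandwidths = bw,
                 axes = axes, years = as.integer(yl)),
            class = "density_map")
}
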