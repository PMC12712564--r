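#!/usr/bin/env Rscript
# Association between the data-shift partition and per-metric performance
# partitions: for each metric's interyear matrix, build its MDS embedding,
# cluster (hierarchical and k-means, k = 2), cross-tabulate the 12 yearly
# labels against the data partition, and apply the two-sided Fisher exact
# test with BH adjustment across metrics.

library(ehrshift)

char_dir <- file.path("results", "characterization")
igt_coords <- read.csv(file.path(char_dir, "igt_data.csv"))
coords <- as.matrix(igt_coords[, -1])
rownames(coords) <- igt_coords$batch
data_partition <- hierarchical_partition(coords, k = 2)

outdir <- file.path("results", "association")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

read_eval <- function(algorithm, metric) {
  M <- as.matrix(read.csv(file.path("results", "models",
                                    sprintf("eval_%s_%s.csv", algorithm,
                                            metric)),
                          row.names = 1, check.names = FALSE))
  structure(list(metric = metric, M = M, labels = rownames(M),
                 thresholded = !(metric %in% c("roc_auc", "pr_auc"))),
            class = "eval_matrix")
}

all_results <- list()
for (algorithm in c("random_forest", "gradient_boosting")) {
  evals <- lapply(stats::setNames(metric_names(), metric_names()),
                  function(m) read_eval(algorithm, m))
  for (method in c("hierarchical", "kmeans")) {
    res <- associate(data_partition, evals, method = method)
    res$algorithm <- algorithm
    all_results[[paste(algorithm, method)]] <- res
    cat(sprintf("\n%s / %s clustering:\n", algorithm, method))
    print(res[, c("metric", "p_raw", "p_adjusted")], row.names = FALSE)
  }
}
out <- do.call(rbind, all_results)
rownames(out) <- NULL
write.csv(out, file.path(outdir, "association_tests.csv"),
          row.names = FALSE)
cat(sprintf("\n%d Fisher tests written to %s\n", nrow(out),
            file.path(outdir, "association_tests.csv")))
cat(sprintf("Raw p <= .05 in %d of %d tests\n", sum(out$p_raw <= 0.05),
            nrow(out)))
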