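#!/usr/bin/env Rscript
# Unsupervised temporal dataset-shift characterization of the simulated
# cohort: data temporal heatmaps (marginal, prior, class-conditional,
# posterior), the FAMD latent space with per-year kernel density maps, and
# IGT projections for the full and class-combined densities. Writes the
# dissimilarity matrices, projections and the 2-cluster data partition.

library(ehrshift)

cohort <- read_admissions(file.path("results", "cohort", "admissions.csv"),
                          file.path("results", "cohort", "codes.csv"))
map <- example_code_map()
features <- harmonize_codes(cohort, map)
batches <- batch_by_year(features)
outdir <- file.path("results", "characterization")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

# Univariate DTHs: class prior, every chapter marginal, and the
# class-conditional / posterior pair for one outcome-linked chapter.
prior <- prior_dth(batches)
write_dth(prior, file.path(outdir, "dth_prior.csv"))
chapters <- grep("^chapter\\.", names(features), value = TRUE)
dth_dir <- file.path(outdir, "dth_marginal")
dir.create(dth_dir, showWarnings = FALSE)
for (v in chapters) write_dth(marginal_dth(batches, v),
                              file.path(dth_dir, paste0(v, ".csv")))
conds <- lapply(c(`0` = 0, `1` = 1), function(cl) {
  conditional_dth(batches, "chapter.Circulatory", cl)
})
write_dth(conds$`1`, file.path(outdir, "dth_circulatory_deceased.csv"))
post <- posterior_dth(conds, prior)
write_dth(post, file.path(outdir, "dth_circulatory_posterior.csv"))

# Multivariate characterization: FAMD to 3 dimensions, per-year KDE maps,
# IGT projections of the full and class-combined densities.
famd <- fit_mixed_reduction(features, d = 3)
cat(sprintf("FAMD: first 3 dimensions explain %.2f%% of total inertia\n",
            100 * sum(famd$evr)))
kde_full <- kde_density_map(famd)
igt_data <- mds_embed(js_dissimilarity(kde_full), k = 3)
write_igt(igt_data, file.path(outdir, "igt_data.csv"))

kde_class <- lapply(c(`0` = 0, `1` = 1), function(cl) {
  keep <- famd$meta$outcome == cl
  ehrshift:::kde_on_grid(famd$scores[keep, , drop = FALSE],
                         famd$meta$year[keep], kde_full)
})
combined <- combine_conditional_maps(kde_class, prior$P)
igt_cond <- mds_embed(js_dissimilarity(combined), k = 3)
write_igt(igt_cond, file.path(outdir, "igt_conditional.csv"))

# Temporal partition of the data IGT (k = 2, the two coding eras).
elbow <- elbow_k(igt_data, k_max = 6)
cat(sprintf("Elbow suggestion: k = %d\n", elbow$k))
partition <- hierarchical_partition(igt_data, k = 2)
cat("Data-shift partition (hierarchical, k = 2):\n")
print(partition$cluster)
jsonlite::write_json(as.list(partition$cluster),
                     file.path(outdir, "data_partition.json"),
                     auto_unbox = TRUE)

png(file.path(outdir, "igt_data.png"), 800, 600)
plot_igt(igt_data, main = "IGT projection of yearly data distributions")
dev.off()
cat("Characterization artifacts written under", outdir, "\n")
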