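#!/usr/bin/env Rscript
# Simulate the study cohort: 12 yearly batches of admissions with a rare
# in-hospital mortality outcome, an ICD-9-style to ICD-10-style coding
# transition at 2014, and a combined covariate + concept shift across it.
# Writes the admission-level CSVs the rest of the analysis ingests.

library(ehrshift)

outdir <- file.path("results", "cohort")
scenario <- default_scenario("combined", n_per_year = 2000, seed = 20080101)
cohort <- generate_cohort(scenario)
paths <- write_cohort(cohort, outdir)

adm <- cohort$admissions
cat(sprintf("Simulated %d admissions over %d years (%d-%d)\n",
            nrow(adm), scenario$n_years, min(adm$year), max(adm$year)))
cat(sprintf("Outcome prevalence: %.4f (target %.4f)\n",
            mean(adm$outcome), mean(scenario$prevalence_by_year)))
cat(sprintf("Code rows: %d; coding systems: %s\n", nrow(cohort$codes),
            paste(sort(unique(cohort$codes$coding_system)), collapse = ", ")))
cat("Written:\n")
for (p in paths) cat("  ", p, "\n")
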