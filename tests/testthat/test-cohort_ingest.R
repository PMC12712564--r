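# Ingestion: schema validation, chapter harmonization, yearly batching.

test_that("read_admissions validates schema and applies the adult criterion", {
  dir <- withr::local_tempdir()
  cohort <- tiny_admissions()
  cohort$admissions$age[1] <- 17          # one minor
  paths <- write_cohort(cohort, dir)
  expect_message(back <- read_admissions(paths[["admissions"]],
                                         paths[["codes"]]),
                 "age < 18")
  expect_equal(nrow(back$admissions), 3)
  expect_false("a1" %in% back$codes$admission_id)

  # Missing required column -> schema error naming it.
  adm2 <- cohort$admissions; adm2$outcome <- NULL
  write.csv(adm2, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(read_admissions(file.path(dir, "bad.csv"), paths[["codes"]]),
               "outcome", class = "schema_error")

  # Orphan code rows -> validation error.
  codes2 <- cohort$codes
  codes2$admission_id[1] <- "ghost"
  write.csv(codes2, file.path(dir, "codes2.csv"), row.names = FALSE)
  expect_error(read_admissions(paths[["admissions"]],
                               file.path(dir, "codes2.csv")),
               "ghost", class = "validation_error")
})

test_that("load_code_map validates structure and rejects conflicts", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "map.csv")
  map <- example_code_map(p)
  loaded <- load_code_map(p)
  expect_gte(length(unique(loaded$coding_system)), 2)
  expect_gte(length(unique(loaded$axis)), 2)

  bad <- rbind(map, data.frame(coding_system = "ICD-9", axis = "diagnosis",
                               code = "01", chapter = "SomethingElse"))
  write.csv(bad, p, row.names = FALSE)
  expect_error(load_code_map(p), class = "mapping_conflict_error")

  writeLines("", p)
  expect_error(load_code_map(p), class = "schema_error")

  # The packaged fixture equals the in-code map.
  pkg_map <- load_code_map(system.file("extdata", "code_map_synthetic.csv",
                                       package = "ehrshift"))
  expect_equal(as.data.frame(pkg_map), as.data.frame(example_code_map()),
               ignore_attr = TRUE)
})

test_that("harmonization collapses multiplicity and merges dialects", {
  ft <- harmonize_codes(tiny_admissions(), tiny_code_map())
  # a1 has ICD-9 4019 and ICD-10 I10, both Circulatory -> indicator 1 not 2.
  expect_equal(ft$chapter.Circulatory[ft$admission_id == "a1"], 1L)
  expect_equal(ft$chapter.Endocrine[ft$admission_id == "a3"], 1L)
  expect_equal(ft$chapter.Circulatory[ft$admission_id == "a3"], 0L)
  expect_true(all(unlist(ft[grep("^chapter\\.", names(ft))]) %in% 0:1))
  expect_equal(nrow(ft), 4)
})

test_that("longest matching prefix wins", {
  adm <- tiny_admissions()
  map <- rbind(tiny_code_map(),
               data.frame(coding_system = "ICD-9", axis = "diagnosis",
                          code = "4019", chapter = "Hypertension"))
  class(map) <- c("code_map", "data.frame")
  ft <- harmonize_codes(adm, map)
  expect_equal(ft$chapter.Hypertension[ft$admission_id == "a2"], 1L)
  # "4011" still falls back to the 3-character prefix chapter.
  expect_equal(ft$chapter.Circulatory[ft$admission_id == "a4"], 1L)
})

test_that("unmapped codes follow the chosen policy", {
  adm <- tiny_admissions()
  adm$codes$code[3] <- "9999"
  expect_error(harmonize_codes(adm, tiny_code_map(), "error"),
               "9999", class = "unmapped_code_error")
  ft <- harmonize_codes(adm, tiny_code_map(), "bucket")
  expect_true("chapter.Unmapped" %in% names(ft))
  expect_equal(ft$chapter.Unmapped[ft$admission_id == "a2"], 1L)
})

test_that("harmonization is idempotent under an identity chapter map", {
  cohort <- generate_cohort(default_scenario("null", n_per_year = 60,
                                             seed = 4))
  map <- example_code_map()
  ft1 <- harmonize_codes(cohort, map)
  # Re-express each admission's chapters as exact "codes" with an identity
  # map: indicators must be unchanged.
  chap_cols <- grep("^chapter\\.", names(ft1), value = TRUE)
  chapters <- attr(ft1, "chapters")
  long <- do.call(rbind, lapply(seq_along(chapters), function(j) {
    hit <- ft1[[chap_cols[j]]] == 1
    if (!any(hit)) return(NULL)
    data.frame(admission_id = ft1$admission_id[hit],
               coding_system = "chapter", axis = "chapter",
               code = chapters[j], stringsAsFactors = FALSE)
  }))
  identity_map <- data.frame(coding_system = "chapter", axis = "chapter",
                             code = chapters, chapter = chapters)
  class(identity_map) <- c("code_map", "data.frame")
  cohort2 <- structure(list(admissions = cohort$admissions, codes = long,
                            scenario = NULL), class = "admission_table")
  ft2 <- harmonize_codes(cohort2, identity_map)
  expect_equal(ft2[chap_cols], ft1[chap_cols], ignore_attr = TRUE)
})

test_that("batching partitions the table by observed year only", {
  ft <- harmonize_codes(tiny_admissions(), tiny_code_map())
  b <- batch_by_year(ft)
  expect_named(b, c("2008", "2009"))
  expect_equal(sum(vapply(b, nrow, 0L)), nrow(ft))

  ft_gap <- ft
  ft_gap$year <- c(2008L, 2008L, 2010L, 2010L)
  expect_named(batch_by_year(ft_gap), c("2008", "2010"))

  ft_one <- ft[ft$year == 2008, ]
  expect_error(batch_by_year(ft_one), class = "insufficient_batches_error")
})
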