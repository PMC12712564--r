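# Cohort ingestion: read admission-level data, harmonize ICD-9/ICD-10 codes
# into merged chapters through a mapping file, one-hot encode, and split
# into yearly batches.

#' Read an admission table from CSV files
#'
#' Expects the two files written by [write_cohort()] (or any files with the
#' same columns). Admissions younger than 18 are removed, mirroring the
#' adult inclusion criterion; the count removed is reported via a message.
#'
#' @param admissions_path CSV with columns admission_id, year, age, gender,
#'   ethnicity, outcome.
#' @param codes_path CSV with columns admission_id, coding_system, axis, code.
#' @return an `admission_table`.
#' @export
read_admissions <- function(admissions_path, codes_path) {
  for (p in c(admissions_path, codes_path)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p), "schema_error")
  }
  # Everything reads as character first (schema checked below); numeric
  # columns are converted afterwards so code strings keep leading zeros.
  adm <- utils::read.csv(admissions_path, stringsAsFactors = FALSE,
                         colClasses = "character")
  codes <- utils::read.csv(codes_path, stringsAsFactors = FALSE,
                           colClasses = "character")

  need_adm <- c("admission_id", "year", "age", "gender", "ethnicity", "outcome")
  need_codes <- c("admission_id", "coding_system", "axis", "code")
  miss <- setdiff(need_adm, names(adm))
  if (length(miss)) {
    abort(sprintf("admissions file missing column(s): %s",
                  paste(miss, collapse = ", ")), "schema_error")
  }
  miss <- setdiff(need_codes, names(codes))
  if (length(miss)) {
    abort(sprintf("codes file missing column(s): %s",
                  paste(miss, collapse = ", ")), "schema_error")
  }
  adm$year <- as.integer(adm$year)
  adm$age <- as.numeric(adm$age)
  adm$outcome <- as.integer(adm$outcome)
  if (anyDuplicated(adm$admission_id)) {
    abort("admission_id values are not unique", "validation_error")
  }
  if (!all(adm$outcome %in% c(0L, 1L))) {
    abort("outcome must be binary 0/1", "validation_error")
  }
  orphans <- setdiff(codes$admission_id, adm$admission_id)
  if (length(orphans)) {
    abort(sprintf("code rows reference unknown admission_ids: %s",
                  paste(utils::head(orphans, 5), collapse = ", ")),
          "validation_error")
  }

  minors <- adm$age < 18
  if (any(minors)) {
    message(sprintf("removed %d admission(s) with age < 18", sum(minors)))
    keep <- adm$admission_id[!minors]
    adm <- adm[!minors, , drop = FALSE]
    codes <- codes[codes$admission_id %in% keep, , drop = FALSE]
  }
  structure(list(admissions = adm, codes = codes, scenario = NULL),
            class = "admission_table")
}

#' Load a code-to-chapter mapping file
#'
#' The mapping CSV has columns `coding_system, axis, code, chapter`, where
#' `code` is an exact code or a dot-free prefix; the longest matching prefix
#' wins at harmonization time. A code (or prefix) may not resolve to two
#' chapters within one (coding_system, axis).
#'
#' @param path CSV path.
#' @return a `code_map` data frame.
#' @export
load_code_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path),
                                "schema_error")
  map <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                  colClasses = "character"),
                  error = function(e) abort("unreadable mapping file",
                                            "schema_error"))
  need <- c("coding_system", "axis", "code", "chapter")
  if (!all(need %in% names(map)) || nrow(map) == 0) {
    abort("code map must have columns coding_system, axis, code, chapter and at least one row",
          "schema_error")
  }
  if (any(!nzchar(map$chapter))) {
    abort("empty chapter labels in code map", "schema_error")
  }
  key <- paste(map$coding_system, map$axis, map$code, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup & stats::ave(map$chapter, key,
                           FUN = function(z) length(unique(z))) > 1)) {
    bad <- unique(map$code[dup])
    abort(sprintf("conflicting chapters for code(s): %s",
                  paste(utils::head(bad, 5), collapse = ", ")),
          "mapping_conflict_error")
  }
  map <- map[!duplicated(key), , drop = FALSE]
  class(map) <- c("code_map", "data.frame")
  map
}

#' Example synthetic code map matching the generator's chapter catalogue
#'
#' Returns the mapping (prefix rows for both coding dialects and both axes)
#' as a `code_map`; `write = TRUE` also writes it as CSV so file-based
#' ingestion can be exercised. The packaged copy lives at
#' `system.file("extdata", "code_map_synthetic.csv", package = "ehrshift")`.
#'
#' @param path optional CSV output path.
#' @return a `code_map` data frame.
#' @export
example_code_map <- function(path = NULL) {
  cat <- chapter_catalogue()
  map <- rbind(
    data.frame(coding_system = "ICD-9", axis = cat$axis,
               code = cat$icd9_prefix, chapter = cat$chapter,
               stringsAsFactors = FALSE),
    data.frame(coding_system = "ICD-10", axis = cat$axis,
               code = cat$icd10_prefix, chapter = cat$chapter,
               stringsAsFactors = FALSE)
  )
  if (!is.null(path)) utils::write.csv(map, path, row.names = FALSE)
  class(map) <- c("code_map", "data.frame")
  map
}

# Resolve raw codes to chapters by longest-prefix match within each
# (coding_system, axis); returns a character vector with NA for unmapped.
resolve_chapters <- function(codes, map) {
  out <- rep(NA_character_, nrow(codes))
  grp_code <- paste(codes$coding_system, codes$axis, sep = "\r")
  grp_map <- paste(map$coding_system, map$axis, sep = "\r")
  for (g in unique(grp_code)) {
    idx <- which(grp_code == g)
    sub <- map[grp_map == g, , drop = FALSE]
    if (nrow(sub) == 0) next
    lens <- sort(unique(nchar(sub$code)), decreasing = TRUE)
    remaining <- idx
    for (L in lens) {
      if (!length(remaining)) break
      lookup <- sub$chapter[nchar(sub$code) == L]
      names(lookup) <- sub$code[nchar(sub$code) == L]
      hit <- lookup[substr(codes$code[remaining], 1L, L)]
      found <- !is.na(hit)
      out[remaining[found]] <- unname(hit[found])
      remaining <- remaining[!found]
    }
  }
  out
}

#' Harmonize codes into one-hot chapter indicators
#'
#' Produces one row per admission with a binary indicator per mapped chapter
#' (1 iff the admission has at least one code resolving to that chapter;
#' multiplicity collapses), numeric age, and gender/ethnicity kept as
#' factors with levels fixed across the whole table.
#'
#' @param admissions an `admission_table`.
#' @param map a `code_map`.
#' @param unmapped_policy `"error"` (fail listing distinct unmapped codes) or
#'   `"bucket"` (route unmapped codes to an `"Unmapped"` chapter).
#' @return a `feature_table` data frame: admission_id, year, outcome, age,
#'   gender, ethnicity, then one `chapter.` column per chapter.
#' @export
harmonize_codes <- function(admissions, map,
                            unmapped_policy = c("error", "bucket")) {
  unmapped_policy <- match.arg(unmapped_policy)
  adm <- admissions$admissions
  codes <- admissions$codes

  chapters <- sort(unique(map$chapter))
  resolved <- resolve_chapters(codes, map)
  if (anyNA(resolved)) {
    if (unmapped_policy == "error") {
      bad <- sort(unique(codes$code[is.na(resolved)]))
      abort(sprintf("unmapped code(s): %s%s",
                    paste(utils::head(bad, 10), collapse = ", "),
                    if (length(bad) > 10) " ..." else ""),
            "unmapped_code_error")
    }
    resolved[is.na(resolved)] <- "Unmapped"
    chapters <- c(chapters, "Unmapped")
  }

  ind <- matrix(0L, nrow = nrow(adm), ncol = length(chapters),
                dimnames = list(NULL, chapters))
  if (nrow(codes) > 0) {
    i <- match(codes$admission_id, adm$admission_id)
    j <- match(resolved, chapters)
    ind[cbind(i, j)] <- 1L
  }
  colnames(ind) <- paste0("chapter.", make.names(chapters))

  out <- data.frame(
    admission_id = adm$admission_id,
    year = adm$year,
    outcome = adm$outcome,
    age = adm$age,
    gender = factor(adm$gender),
    ethnicity = factor(adm$ethnicity),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(ind))
  attr(out, "chapters") <- chapters
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Split a feature table into yearly batches
#'
#' @param features a `feature_table`.
#' @return a named list of per-year feature tables, years ascending; the
#'   union of batches equals the input and batches are disjoint. Only
#'   observed years appear (gaps produce no empty batches).
#' @export
batch_by_year <- function(features) {
  years <- sort(unique(features$year))
  if (length(years) < 2) {
    abort("at least 2 distinct years are required to form temporal batches",
          "insufficient_batches_error")
  }
  batches <- lapply(years, function(y) {
    features[features$year == y, , drop = FALSE]
  })
  names(batches) <- years
  batches
}

# Feature-matrix view for classifiers: chapter indicators + age +
# one-hot demographics. Columns are stable across batches.
feature_matrix <- function(features) {
  chap <- as.matrix(features[, grep("^chapter\\.", names(features)),
                             drop = FALSE])
  gl <- levels(features$gender)
  el <- levels(features$ethnicity)
  g <- outer(as.character(features$gender), gl, "==") * 1L
  colnames(g) <- paste0("gender.", make.names(gl))
  e <- outer(as.character(features$ethnicity), el, "==") * 1L
  colnames(e) <- paste0("ethnicity.", make.names(el))
  cbind(chap, age = features$age, g, e)
}
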