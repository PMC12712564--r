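# Synthetic EHR cohort generator.
#
# Emulates the structure of an admission-level hospital dataset: ~12 yearly
# batches, a rare binary in-hospital mortality outcome, diagnosis/procedure
# codes grouped into merged chapters, demographics, and an abrupt
# coding-system transition (ICD-9-style to ICD-10-style) at a changepoint
# year. Covariate shift is injected by changing per-chapter code prevalences
# across the changepoint, prior shift by a step in outcome prevalence, and
# concept shift by changing the outcome-given-features log-odds.

# Merged chapter catalogue: 21 chapters (14 diagnosis + 7 procedure), each
# with an ICD-9-style numeric prefix and an ICD-10-style alphanumeric prefix.
chapter_catalogue <- function() {
  diag <- c("Infectious", "Neoplasms", "Endocrine", "Mental", "Nervous",
            "Circulatory", "Respiratory", "Digestive", "Genitourinary",
            "Skin", "Musculoskeletal", "Injury", "Symptoms",
            "Other diagnoses")
  proc <- c("Medical and Surgical", "Imaging", "Administration",
            "Extracorporeal", "Laboratory", "Cardiovascular procedures",
            "Other procedures")
  data.frame(
    chapter = c(diag, proc),
    axis = c(rep("diagnosis", length(diag)), rep("procedure", length(proc))),
    icd9_prefix = c(sprintf("%02d", seq_along(diag)),
                    sprintf("%02d", seq_along(proc))),
    icd10_prefix = c(LETTERS[seq_along(diag)],
                     sprintf("0%s", LETTERS[seq_along(proc)])),
    stringsAsFactors = FALSE
  )
}

# Default per-chapter Bernoulli prevalences (stable, deterministic spread).
default_chapter_rates <- function() {
  cat <- chapter_catalogue()
  rates <- rep(c(0.10, 0.22, 0.35, 0.15, 0.45), length.out = nrow(cat))
  names(rates) <- cat$chapter
  rates
}

# Default outcome log-odds coefficients: a handful of clinically plausible
# chapter effects plus standardized age. Intercept is a starting value only;
# the generator recalibrates it per year to hit the target prevalence.
default_concept_coef <- function() {
  coef <- c(Circulatory = 0.9, Respiratory = 0.7, Neoplasms = 0.8,
            Infectious = 0.6, Symptoms = 0.4, age_z = 0.8)
  list(intercept = -4, coef = coef)
}

default_demographics <- function() {
  list(
    age_mean = 65, age_sd = 17,
    gender_probs = c(F = 0.45, M = 0.55),
    ethnicity_probs = c(White = 0.65, Black = 0.15, Hispanic = 0.10,
                        Other = 0.10)
  )
}

#' Build a preset shift scenario
#'
#' Presets mirror the dataset-shift taxonomy: `"null"` (stationary),
#' `"covariate"` (chapter prevalences change at the changepoint, the
#' outcome model does not), `"prior"` (outcome prevalence steps at the
#' changepoint), `"concept"` (outcome-given-features log-odds change, the
#' feature distribution does not) and `"combined"` (covariate + concept).
#' The default outcome prevalence is 0.0291 in every year, matching a rare
#' in-hospital mortality outcome; the default series spans 12 years from
#' 2008 with the changepoint at 2014 and an ICD-9-style to ICD-10-style
#' coding transition for every preset with a changepoint.
#'
#' @param kind one of `"null"`, `"covariate"`, `"prior"`, `"concept"`,
#'   `"combined"`.
#' @param n_per_year admissions per yearly batch (>= 50).
#' @param seed integer seed; the cohort is a pure function of the scenario.
#' @return a `shift_scenario` object (a validated list).
#' @export
default_scenario <- function(kind = c("null", "covariate", "prior",
                                      "concept", "combined"),
                             n_per_year = 1000L, seed = 1L) {
  if (length(kind) != 1L || !kind %in% c("null", "covariate", "prior",
                                         "concept", "combined")) {
    abort(sprintf("unknown scenario kind '%s'", paste(kind, collapse = "/")),
          "configuration_error")
  }
  if (n_per_year < 50) {
    abort("n_per_year must be >= 50", "configuration_error")
  }

  n_years <- 12L
  start_year <- 2008L
  changepoint <- if (kind == "null") NA_integer_ else 2014L

  rates_pre <- default_chapter_rates()
  rates_post <- rates_pre
  coef_pre <- default_concept_coef()
  coef_post <- coef_pre
  prevalence <- rep(0.0291, n_years)

  if (kind %in% c("covariate", "combined")) {
    # Redistribution of chapter prevalences, echoing an ICD-version update:
    # imaging/administration-style chapters rise, legacy buckets fall.
    up <- c("Imaging", "Extracorporeal", "Administration")
    down <- c("Other procedures", "Cardiovascular procedures")
    rates_post[up] <- pmin(rates_post[up] + 0.30, 0.95)
    rates_post[down] <- pmax(rates_post[down] - 0.30, 0.02)
  }
  if (kind == "prior") {
    post_years <- (start_year:(start_year + n_years - 1L)) >= changepoint
    prevalence[post_years] <- 0.06
  }
  if (kind %in% c("concept", "combined")) {
    coef_post$coef[c("Circulatory", "Respiratory", "Neoplasms")] <-
      -coef_pre$coef[c("Circulatory", "Respiratory", "Neoplasms")]
  }

  scenario <- structure(list(
    kind = kind,
    start_year = start_year,
    n_years = n_years,
    n_per_year = as.integer(n_per_year),
    prevalence_by_year = prevalence,
    chapter_rates_pre = rates_pre,
    chapter_rates_post = rates_post,
    concept_coef_pre = coef_pre,
    concept_coef_post = coef_post,
    changepoint_year = changepoint,
    demographics = default_demographics(),
    coding_transition = !is.na(changepoint),
    seed = as.integer(seed)
  ), class = "shift_scenario")
  validate_scenario(scenario)
  scenario
}

#' Validate a shift scenario
#'
#' @param scenario a `shift_scenario` list.
#' @return the scenario, invisibly, or an error.
#' @export
validate_scenario <- function(scenario) {
  s <- scenario
  if (length(s$prevalence_by_year) != s$n_years) {
    abort("prevalence_by_year must have length n_years", "configuration_error")
  }
  probs <- c(s$prevalence_by_year, s$chapter_rates_pre, s$chapter_rates_post,
             s$demographics$gender_probs, s$demographics$ethnicity_probs)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]", "configuration_error")
  }
  if (!identical(names(s$chapter_rates_pre), names(s$chapter_rates_post))) {
    abort("pre/post chapter rate vectors must cover the same chapters",
          "configuration_error")
  }
  if (!is.na(s$changepoint_year)) {
    last_year <- s$start_year + s$n_years - 1L
    if (s$changepoint_year <= s$start_year || s$changepoint_year > last_year) {
      abort("changepoint_year must lie strictly inside the observed years",
            "configuration_error")
    }
  }
  # Degenerate: outcome coefficients only on chapters that can never occur.
  for (cc in list(s$concept_coef_pre, s$concept_coef_post)) {
    on_chapters <- intersect(names(cc$coef), names(s$chapter_rates_pre))
    if (length(on_chapters) > 0 &&
        all(s$chapter_rates_pre[on_chapters] == 0) &&
        all(s$chapter_rates_post[on_chapters] == 0) &&
        all(cc$coef[setdiff(names(cc$coef), on_chapters)] == 0)) {
      abort("outcome coefficients act only on chapters with zero prevalence",
            "configuration_error")
    }
  }
  invisible(scenario)
}

# Solve for the yearly intercept a such that mean(plogis(a + eta)) == target.
calibrate_intercept <- function(eta, target) {
  f <- function(a) mean(stats::plogis(a + eta)) - target
  stats::uniroot(f, lower = -30, upper = 10, tol = 1e-10)$root
}

#' Generate a synthetic admission cohort
#'
#' Draws `n_years * n_per_year` admissions. Chapter indicators are Bernoulli
#' with the period's rates; the outcome is Bernoulli with logit
#' `intercept_t + coef . x`, the intercept recalibrated by root finding each
#' year so the realized marginal prevalence matches `prevalence_by_year`.
#' With `coding_transition`, code strings switch from ICD-9-style numeric to
#' ICD-10-style alphanumeric at the changepoint while mapping to the same
#' merged chapters. Ages are truncated-normal, clipped to >= 18.
#'
#' @param scenario a `shift_scenario`.
#' @return an `admission_table`: list with data frames `admissions`
#'   (admission_id, year, age, gender, ethnicity, outcome) and `codes`
#'   (admission_id, coding_system, axis, code), plus the scenario.
#' @export
generate_cohort <- function(scenario) {
  validate_scenario(scenario)
  s <- scenario
  cat <- chapter_catalogue()
  years <- s$start_year:(s$start_year + s$n_years - 1L)

  with_seed(s$seed, {
    adm_list <- vector("list", length(years))
    code_list <- vector("list", length(years))
    for (t in seq_along(years)) {
      year <- years[t]
      n <- s$n_per_year
      post <- !is.na(s$changepoint_year) && year >= s$changepoint_year
      rates <- if (post) s$chapter_rates_post else s$chapter_rates_pre
      cc <- if (post) s$concept_coef_post else s$concept_coef_pre

      id <- sprintf("adm_%d_%05d", year, seq_len(n))
      age <- pmax(18, round(stats::rnorm(n, s$demographics$age_mean,
                                         s$demographics$age_sd)))
      gender <- sample(names(s$demographics$gender_probs), n, replace = TRUE,
                       prob = s$demographics$gender_probs)
      ethnicity <- sample(names(s$demographics$ethnicity_probs), n,
                          replace = TRUE,
                          prob = s$demographics$ethnicity_probs)

      # Chapter indicator matrix: n x n_chapters.
      X <- matrix(stats::rbinom(n * length(rates), 1L,
                                rep(rates, each = n)),
                  nrow = n, dimnames = list(NULL, names(rates)))

      # Outcome via the period's logistic model, intercept calibrated to the
      # year's target prevalence.
      age_z <- (age - s$demographics$age_mean) / s$demographics$age_sd
      feats <- cbind(X, age_z = age_z)
      use <- intersect(names(cc$coef), colnames(feats))
      eta <- as.vector(feats[, use, drop = FALSE] %*% cc$coef[use])
      a <- calibrate_intercept(eta, s$prevalence_by_year[t])
      outcome <- stats::rbinom(n, 1L, stats::plogis(a + eta))

      adm_list[[t]] <- data.frame(
        admission_id = id, year = year, age = age, gender = gender,
        ethnicity = ethnicity, outcome = outcome, stringsAsFactors = FALSE
      )

      # Codes: for every (admission, chapter) with indicator 1 emit 1-3 code
      # strings in the period's dialect; raw codes carry random suffixes so
      # multiplicity and prefix mapping are both exercised downstream.
      hits <- which(X == 1L, arr.ind = TRUE)
      if (nrow(hits) > 0) {
        n_codes <- 1L + stats::rpois(nrow(hits), 0.5)
        row_adm <- rep(hits[, 1L], n_codes)
        row_chp <- rep(hits[, 2L], n_codes)
        use_icd10 <- s$coding_transition && post
        prefix <- if (use_icd10) cat$icd10_prefix[row_chp] else
          cat$icd9_prefix[row_chp]
        suffix <- sprintf("%02d", sample.int(99L, length(row_adm),
                                             replace = TRUE))
        code_list[[t]] <- data.frame(
          admission_id = id[row_adm],
          coding_system = if (use_icd10) "ICD-10" else "ICD-9",
          axis = cat$axis[row_chp],
          code = paste0(prefix, suffix),
          stringsAsFactors = FALSE
        )
      }
    }
    structure(list(
      admissions = do.call(rbind, adm_list),
      codes = do.call(rbind, code_list),
      scenario = s
    ), class = "admission_table")
  })
}

#' Write a cohort to plain-text files
#'
#' Writes `admissions.csv`, `codes.csv` and (when present) the scenario as
#' `scenario.json` into `dir`.
#'
#' @param cohort an `admission_table`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  adm_path <- file.path(dir, "admissions.csv")
  codes_path <- file.path(dir, "codes.csv")
  utils::write.csv(cohort$admissions, adm_path, row.names = FALSE)
  utils::write.csv(cohort$codes, codes_path, row.names = FALSE)
  paths <- c(admissions = adm_path, codes = codes_path)
  if (!is.null(cohort$scenario)) {
    sc_path <- file.path(dir, "scenario.json")
    sc <- unclass(cohort$scenario)
    jsonlite::write_json(sc, sc_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    paths <- c(paths, scenario = sc_path)
  }
  invisible(paths)
}

#' @export
print.shift_scenario <- function(x, ...) {
  cat(sprintf("<shift_scenario> kind=%s years=%d-%d n/year=%d changepoint=%s\n",
              x$kind, x$start_year, x$start_year + x$n_years - 1L,
              x$n_per_year,
              ifelse(is.na(x$changepoint_year), "none", x$changepoint_year)))
  invisible(x)
}

#' @export
print.admission_table <- function(x, ...) {
  cat(sprintf("<admission_table> %d admissions, %d code rows, years %s-%s\n",
              nrow(x$admissions), nrow(x$codes),
              min(x$admissions$year), max(x$admissions$year)))
  invisible(x)
}
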