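# Shared fixtures, built in code at test time.

# Small harmonized yearly batches from a preset scenario.
make_batches <- function(kind = "null", n_per_year = 200, seed = 1) {
  cohort <- generate_cohort(default_scenario(kind, n_per_year = n_per_year,
                                             seed = seed))
  batch_by_year(harmonize_codes(cohort, example_code_map()))
}

# A tiny hand-written admission table (no generator involved).
tiny_admissions <- function() {
  adm <- data.frame(
    admission_id = c("a1", "a2", "a3", "a4"),
    year = c(2008L, 2008L, 2009L, 2009L),
    age = c(40, 70, 55, 63),
    gender = c("F", "M", "F", "M"),
    ethnicity = c("White", "Black", "White", "Other"),
    outcome = c(0L, 1L, 0L, 0L),
    stringsAsFactors = FALSE
  )
  codes <- data.frame(
    admission_id = c("a1", "a1", "a2", "a3", "a4"),
    coding_system = c("ICD-9", "ICD-10", "ICD-9", "ICD-9", "ICD-9"),
    axis = rep("diagnosis", 5),
    code = c("4019", "I10", "4019", "25000", "4011"),
    stringsAsFactors = FALSE
  )
  structure(list(admissions = adm, codes = codes, scenario = NULL),
            class = "admission_table")
}

tiny_code_map <- function() {
  map <- data.frame(
    coding_system = c("ICD-9", "ICD-9", "ICD-10"),
    axis = "diagnosis",
    code = c("401", "250", "I10"),
    chapter = c("Circulatory", "Endocrine", "Circulatory"),
    stringsAsFactors = FALSE
  )
  class(map) <- c("code_map", "data.frame")
  map
}

# Independent brute-force two-sided Fisher p for a 2x2 table: enumerate all
# margin-compatible tables directly from factorials.
fisher_brute <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  prob_of <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- r2 - cc
    if (min(b, cc, d) < 0) return(NA_real_)
    exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
          lfactorial(n - c1) - lfactorial(n) - lfactorial(a) -
          lfactorial(b) - lfactorial(cc) - lfactorial(d))
  }
  probs <- vapply(0:min(r1, c1), prob_of, 0)
  probs <- probs[!is.na(probs)]
  p_obs <- prob_of(tab[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-cluster partition object from a year -> label vector (for cross_tab
# tests without running a clustering).
manual_partition <- function(years, labels) {
  structure(list(years = as.character(years),
                 cluster = stats::setNames(as.integer(labels),
                                           as.character(years)),
                 method = "manual", k = length(unique(labels)),
                 meta = list()),
            class = "temporal_partition")
}
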