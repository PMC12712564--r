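---
title: "Characterizing temporal dataset shifts and their association with model performance"
author: "ehrshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing temporal dataset shifts and their association with model performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrshift)
```

## The problem

Clinical prediction models are trained on retrospective electronic health
record (EHR) data and deployed prospectively, but the joint distribution
p(x, y) of features and outcome drifts over calendar time. Three canonical
mechanisms are distinguished:

- **covariate shift** — the marginal feature distribution p(x) changes
  while p(y|x) is stable (e.g. a coding-system update redistributes which
  diagnosis chapters are recorded);
- **prior probability shift** — the outcome rate p(y) changes;
- **concept shift** — the conditional p(y|x) linking features to the
  outcome changes.

`ehrshift` implements an *unsupervised* characterization of these shifts on
admission-level EHR data batched by year, and then asks whether the
temporal structure found in the data alone predicts the temporal structure
of model performance: if years cluster into eras by their data
distributions, do interyear model evaluations cluster into the same eras?

The package ships a synthetic cohort generator so the whole analysis runs
end-to-end, reproducibly, without access to any restricted clinical
database.

## Data temporal heatmaps and IGT projections

For each yearly batch we estimate univariate distributions and store them
as *data temporal heatmaps* (DTHs): value-by-year probability matrices for
the marginal p(x), the prior p(y), the class-conditionals p(x|y), and the
Bayes posterior p(y|x) = p(x|y) p(y) / Σ p(x|y') p(y'). Counts are
smoothed with a Laplace parameter α (default 0.5, a Jeffreys-style prior),
so that no cell is exactly zero before dissimilarity computation; at α = 0
the DTHs satisfy the law of total probability exactly, which the tests
assert. Numeric variables (age) are discretized into 20 equal-width bins
over the pooled range; the discretization is a declared default, not an
estimate of any particular dataset's structure.

The *information-geometric temporal* (IGT) projection embeds the yearly
batches as points whose pairwise distances are dissimilarities between the
batches' estimated distributions. We use the square root of the
Jensen-Shannon divergence (base 2), which is bounded in [0, 1], symmetric
and a metric, and embed with classical (Torgerson) multidimensional
scaling: deterministic, and exact when the dissimilarities are Euclidean.
Negative eigenvalues are truncated at zero with the discarded mass
reported as a diagnostic; axis signs are fixed (first batch nonnegative)
so projections are reproducible. Trends appear as flowing sequences of
yearly points, abrupt shifts as gaps, and eras as clusters.

## Multivariate characterization: FAMD + per-year KDE

Chapters, demographics and age are mixed-type, so the multivariate view
uses factorial analysis of mixed data (FAMD): numeric columns are
standardized (population scaling, so duplicating rows leaves the fit
invariant), categorical columns are expanded to indicators scaled by the
inverse square root of the category proportion and centered, and the
combined matrix is decomposed by SVD. Binary chapter indicators are
treated as two-level categoricals, the FAMD convention for one-hot data.
We keep the first 3 dimensions by default — the exploratory target is
temporal structure, not full variance recovery — and store all scaling
parameters so out-of-sample projection exactly reproduces training scores.

Per year, a Gaussian product-kernel density is evaluated on a fixed grid
spanning the pooled coordinate range plus a 5% margin and renormalized to
a probability mass vector; the year-by-year Jensen-Shannon dissimilarities
of these mass vectors feed the IGT. Bandwidths follow Scott's rule per
dimension per year and are recorded for reproducibility. The grid uses 32
points per dimension for d ≤ 2 and 16 for d = 3 (4096 cells), bounding
memory while leaving the pairwise dissimilarities stable: doubling the
grid changes them by under 5% on smooth data, which is tested. Kernel,
bandwidth rule and resolution are declared defaults — the dissimilarities,
not the densities themselves, are the product.

For concept-oriented views, class-conditional KDE maps are combined into a
single map as the prior-weighted mixture, renormalized per year. Because
the positive class is rare, small cohorts can have years with fewer than
two (or zero) positive admissions: a single point is smoothed with the
full-population bandwidth for that year, and an empty class-year falls
back to a uniform column with a warning. The primary
`kde_density_map()` contract still requires two points per year.

## Yearly models and interyear evaluation

Each yearly batch is split 80/20 into development and test, and the
development part 70/30 into pure training and validation (56% / 24% / 20%
of the year), stratified by outcome and fully seeded. Hyperparameters for
the random forest and gradient boosting families are chosen by grid
search: one model per year per grid point, scored by ROC-AUC on the
same-year validation set, selecting the highest mean across years (ties
prefer the smaller model). The default grids contain the reference
configurations of 500 trees at depth 9 (random forest) and 100 estimators
at depth 2 (gradient boosting).

Because the outcome is rare, thresholded metrics use a Youden-index cut
J = sensitivity + specificity − 1 instead of 0.5, selected over the
distinct predicted scores on the *most recent* year's validation data —
the vantage point of someone deploying today's model on historical and
future batches alike. The threshold is selected per model by default (each
model's own scores on that validation set); a single global threshold is
available behind a flag. Thresholds are restricted to the open interval
(0, 1), and if the latest year's validation set is single-class the
selection falls back to the latest usable year, with a warning.

Every model is evaluated on every year's held-out test rows — never on
training rows, which the tests audit — yielding 12 × 12 matrices for
ROC-AUC, PR-AUC, precision, recall, accuracy and macro-F1. Ranking
metrics on a single-class test year are reported as undefined (NA), not
zero; precision with no predicted positives is reported as 0 by
convention.

## Association testing

The interyear matrix M for a metric is turned into a year dissimilarity
D[i, j] = 1 − (M[i, j] + M[j, i]) / 2 (years whose models transfer well
onto each other are close); an alternative profile mode — normalized
Manhattan distance between each year's concatenated row and column
performance profiles — is provided because the construction is not
uniquely determined by the idea of "an IGT for performance", and the mode
used is recorded in every result. The dissimilarity is embedded with MDS
(k = 3) and partitioned into k = 2 clusters, matching the two coding
eras; the elbow curve (within-cluster Manhattan dispersion around
componentwise medians, which makes the curve provably non-increasing over
nested cuts) is advisory and never silently overrides the configured k.
Hierarchical clustering uses complete linkage on Manhattan distances;
k-means uses Lloyd iterations initialized at the first and last years'
coordinates, following the natural temporal ordering, and is therefore
deterministic.

The data partition and each metric's performance partition are
cross-tabulated over the 12 yearly labels and tested with the two-sided
Fisher exact test under the probability-ordering rule (all tables with the
observed margins whose probability does not exceed the observed table's,
ties included) — stated explicitly because two-sided conventions vary.
Only 2 × 2 tables are supported; larger k raises an explicit error rather
than a silent approximation. P-values are adjusted across metrics with
Benjamini-Hochberg. Cross-tabulating years (n = 12) is a deliberate
choice: the partitions being compared are partitions of years.

## The synthetic cohort generator

`default_scenario()` encodes the study conditions: 12 yearly batches from
2008, outcome prevalence 0.0291 in every year, 21 merged chapters (14
diagnosis, 7 procedure), ages truncated-normal (mean 65, sd 17, clipped to
≥ 18), and a changepoint at 2014 with an ICD-9-style to ICD-10-style
dialect switch for every non-null preset. The outcome is Bernoulli with
logit = intercept + coef·x over chapter indicators and standardized age —
the simplest generative model with a well-defined p(y|x) — and the
intercept is recalibrated by root finding each year so the realized
prevalence matches the target exactly in expectation.

Shift presets change exactly one mechanism each: `covariate` moves five
procedure-chapter rates by ±0.30 absolute across the changepoint (none of
them outcome-linked, so p(y|x) is untouched); `prior` steps prevalence
from 0.0291 to 0.06; `concept` flips the sign of three outcome-linked
chapter coefficients while leaving p(x) unchanged; `combined` applies
covariate and concept together. The magnitudes are calibration knobs
chosen once to represent a strong, unambiguous shift — the kind a
coding-system migration plausibly produces — and are not estimates of any
real system's effect size. Code strings carry random suffixes under
chapter-level prefixes in both dialects, so the mapping path (longest
prefix wins) is genuinely exercised; chapters, not raw codes, carry the
signal.

What the generator does *not* emulate: deidentification-driven year
uncertainty, within-year seasonality, correlated chapter co-occurrence,
admission-level repeat patients, or gradual drifts. Passing tests
therefore show that the pipeline detects the injected abrupt
mechanism-specific shifts and stays calibrated under stationarity — not
that it detects every shift structure real EHR data can produce.

## Replicated experiments and problem sizes

Two replicated experiments summarize the pipeline's behavior, at sizes
chosen to keep a full run on one core comfortably inside an interactive
session while leaving the conclusions stable across seeds:

- **changepoint recovery** — 20 seeded replicates of the strong combined
  scenario at 2000 admissions/year; per replicate we record whether the
  2-cluster partition of the data IGT splits the years exactly at the
  changepoint and whether the ROC-AUC matrix's within-period mean exceeds
  its cross-period mean;
- **null calibration** — 200 seeded replicates of the stationary scenario
  at 1000 admissions/year; per replicate the full association pipeline
  runs and the raw Fisher p-values are recorded. The per-metric frequency
  of p ≤ .05 estimates the false-association rate, expected at or below
  the nominal 5% given the exact test's conservatism (it need not be far
  below: the data partition and the performance partitions are computed
  from the *same* sampled years, so they are not strictly independent
  under the null). The construction is doubly conservative — with 12
  labels, p ≤ .05 essentially requires near-perfect partition agreement,
  and complete linkage on unstructured embeddings often produces
  singleton clusters for which no metric can reach significance — so for
  metrics whose interyear matrices are nearly constant (accuracy under a
  rare outcome, for instance) the rate can fall to zero at this number of
  replicates.

One master seed fans out to per-stage and per-replicate seeds through a
fixed integer hash (`derive_seed()`), so any stage can be reproduced in
isolation and results are independent of evaluation order.

## Numerical and degenerate-input conventions

- 0·log 0 is treated as 0 throughout; Jensen-Shannon values are clipped at
  0 before the square root.
- Fisher p-values are clamped at 1 (tied-probability sums can exceed 1 by
  machine epsilon); equal-probability tables are ranked with a 1e-7
  relative tolerance, the same convention `stats::fisher.test` uses.
- Per-year distribution columns must sum to 1 within 1e-6 before
  dissimilarity computation; violations raise a normalization error
  rather than being silently renormalized.
- Constant feature columns are dropped from the FAMD with a warning;
  requesting more dimensions than the matrix rank is an error.
- Degenerate clustering inputs (all-identical coordinates) produce a
  deterministic tie-broken hierarchical partition; coincident first/last
  years make the k-means initialization an explicit error.

## Known limitations

- The Fisher test operates on 12 yearly labels, so attainable p-values
  are coarse; associations weaker than the era structure cannot reach
  small p regardless of cohort size.
- The performance dissimilarity is one of several constructions
  compatible with "MDS of the interbatch evaluation matrix"; both
  implemented modes are labeled in outputs to keep the ambiguity visible.
- FAMD is linear; a strongly nonlinear latent structure would call for a
  different reducer. The reduction step is pluggable — any coordinate
  matrix can be passed to `kde_density_map()`.
- Synthetic cohorts are idealized (see above); real-data conclusions
  additionally depend on harmonization quality and on temporal
  identifiers, which the generator takes as exact.
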