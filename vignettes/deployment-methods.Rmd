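---
title: "Methods: confidence-aware ensemble risk prediction on deployed EHR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: confidence-aware ensemble risk prediction on deployed EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Prognostic models developed on curated research registries degrade when
deployed into a hospital's live electronic health record (EHR): variable
names and units differ, structured fields that were complete in the registry
are largely absent at the point of care, laboratory histories are shorter,
and the input distributions drift over time. `ehrisk` packages the
machinery needed to deploy, validate and monitor a high-dimensional
clinical risk model under those conditions, built around the concrete case
of 2-year composite risk of severe infection and/or treatment in newly
diagnosed chronic lymphocytic leukemia (CLL), predicted at a fixed
prediction point three months after diagnosis.

Because patient-level EHR data cannot be shared, every stage is exercised
against a synthetic-EHR generator whose presets encode the two environments
of interest: a `"research"` registry cohort (complete staging data,
roughly ten-year laboratory histories, 2-year composite event rate 33%)
and a `"deployment"` hospital cohort (Binet stage 72.2% missing, IGHV
mutation status 91.1% missing, beta-2-microglobulin 35.8%, FISH 99.5%,
ECOG 100%; under a year of laboratory history; composite rate 40.6%;
P(age >= 65) = 0.764 vs 0.701).

## The model

The predictor is a heterogeneous, feature-bagged ensemble of 28 base
learners: 13 gradient-boosted tree models (native missing-value routing),
7 random forests, 4 extremely randomized trees, 2 elastic-net and 2
plain logistic regressions. Twenty learners model the composite outcome,
five the treatment-only outcome and three the infection-only outcome. Each
learner sees only its own random feature bag (default: half of the
registry, sampled without replacement under the learner's derived seed).

The **soft-vote confidence** for a patient is the unweighted arithmetic
mean of all 28 positive-class probabilities,

$$c_i = \frac{1}{L}\sum_{\ell=1}^{L} \hat p_{\ell}(x_i), \qquad L = 28,$$

read as a confidence score on $[0,1]$: values near 0 or 1 indicate
agreement among the learners, values near 0.5 disagreement. The risk call
is high iff $c_i \ge 0.5$; bands use cutoffs $t_{high} = 0.58$ and
$t_{low} = 0.28$ (packaged defaults, derived originally from the design
requirement that 20% of predictions be high-risk with high confidence and
30% low-risk with high confidence; `derive_thresholds()` reproduces that
derivation as upper/lower empirical quantiles). A recalibrated
$t_{high} = 0.65$ is supported for as-is-missingness cohorts; raising the
cutoff can only shrink the high-confidence high-risk set.

### Missingness, in three layers

1. **Feature layer.** Counting features encode absence as 0; a
   days-since-latest feature encodes recency (large = stale, `NA` = never
   measured); value aggregates (min/median over a window) are `NA` on empty
   windows; baseline categoricals are one-hot encoded with an explicit
   `"unknown"` indicator, so exactly one indicator per variable is active
   for every patient.
2. **Algorithm layer.** Boosted trees receive `NA` directly and route it in
   each split; all other families use median imputation fitted on training
   data only.
3. **Ensemble layer.** Feature bagging plus family and outcome diversity
   decorrelate learner errors, and the confidence score flags patients
   whose missingness pattern undermines the prediction.

A consequence is the 100%-coverage contract: `predict()` returns a
prediction for every patient under any missingness pattern, in contrast to
a five-variable comparator index (age > 65: 1, Binet B/C: 1, β2M > 4 mg/L:
2, IGHV unmutated: 2, del(17p)/TP53: 4; categories 0–1/2–3/4–5/6–10),
which in complete-case mode produces no score when any input is missing
and collapses to near-zero coverage under the deployment missingness
profile.

### Personalized risk factors

Per-feature contributions use occlusion-to-missing: the contribution of
feature $f$ is the confidence on the original row minus the confidence
with $f$ replaced by its missing representation (0 for counts and one-hot
indicators, `NA` otherwise). This reuses the model's own missingness
machinery, is model-agnostic and deterministic; ties rank by feature id.
The top five positive and top five negative contributions form the
clinician-facing risk-factor lists. These contributions are also the probe
used to localize harmonization errors (below).

## Temporal feature engine

Calendar phrases are pinned to integer days: 3 months = 92, 2 years = 730,
7 years = 2557. Windows are closed intervals $[pp - W,\ pp]$; events after
the prediction point never contribute (property-tested by deleting them and
asserting bitwise equality of the matrix). The default registry emits, per
laboratory variable, {min, median, count, days-since-latest} over 92- and
2557-day windows; blood cultures get {count, days-since-latest} over 365
and 2557 days; baselines one-hot blocks. With the default 33-lab panel
this yields 294 features — an approximation, at configurable scale, of the
production model's 228-feature/84-variable design, whose exact list is not
public; an externally supplied registry is accepted. Ties at identical
timestamps aggregate over all tied values (mean for "latest").

## Synthetic-EHR generator

The generator is first-class, tested code, not a fixture. Outcomes follow
the simplest competing-risks construction able to hit the preset rates:
two independent cause-specific exponential clocks (infection, treatment)
with per-day rates $\lambda_k(x) = \exp(\beta_{0k} + x^\top\beta)$. The
covariates entering the linear predictor are the baseline categories
(Binet, IGHV, β2M, FISH, age ≥ 65); because they are finite and
independent, the expected 2-year composite rate has a closed form, and the
shared baseline intercept is calibrated by root finding so the preset rate
(33% / 40.6%) is met exactly in expectation. The treatment share of events
matches the reported first-event split (14.9/18.1 research, 17.5/23.2
deployment). Administrative censoring is uniform on 1–5 years after the
prediction point; empirical rates are therefore measured on patients whose
follow-up covers the horizon.

Laboratory series are stationary log-normal with per-variable levels and
~4 samples/patient-year; a subset of markers (lymphocytes, CRP, LDH,
ferritin, leukocytes, IgM) load on the latent linear predictor so that
laboratory features carry genuine prognostic signal. Values are rounded to
12 significant digits — finite measurement precision, which also makes a
correct linear unit conversion exactly invertible in floating point.
History depth is uniform (8–12 years research, 0.25–1 year deployment);
the research preset additionally drops each laboratory variable wholesale
per patient with probability 0.22, reflecting that the multi-hospital
registry had roughly double the per-patient lab missingness of the
deployment site. Dates are integer day offsets from a fixed epoch. The
latent risk is written only to a generator-side truth file, never to the
exported tables. Identical (spec, seed) reproduce cohorts byte-for-byte.

What the generator does **not** emulate: autocorrelated laboratory
trajectories, treatment-line pharmacology, seasonal infection dynamics,
correlated missingness across variables (each variable is masked
independently), and record duplication. Passing tests on synthetic cohorts
therefore demonstrate the machinery's correctness and directional
behaviour, not clinical performance on real data. One visible consequence:
with independent masking, joint availability of all five comparator inputs
is the product of the marginals (~0.01% under the deployment profile),
below the 0.63% a real EHR shows where missingness is correlated — the
qualitative collapse is the tested property.

## Harmonization by prediction matching

Source extracts are canonicalized through two many-to-one dictionaries —
names (source label → canonical variable) and units (linear transform,
canonical = factor·source + offset; factor ≠ 0; nonlinear conversions out
of scope). Unmapped rows are routed to a report, never silently dropped;
dictionary repair is deliberately human-in-the-loop. Validation does not
compare tables but predictions: for the same patients, the model must
produce the same risk call, a confidence difference within tolerance
(default 0 — bit-identical, which the 12-significant-digit canonicalization
makes attainable; a float tolerance flag exists for cross-platform drift),
and identical top-5 up/down risk-factor lists. Mismatches are localized by
comparing occlusion contributions feature-by-feature across the two
sources and mapping implicated features back to variables, ranked by the
number of affected patients; a single corrupted unit factor reliably ranks
its variable first. `harmonization_cycle()` iterates
harmonize → match → localize with an audit trail until perfect match or an
iteration bound.

## Benchmarking

Outcome labelling applies the deployment rule: positive if the composite
first event falls within 730 days of the prediction point; negative if
event-free with follow-up ≥ 730 days; otherwise excluded from
classification but retained censored for survival analysis; events dated
before the prediction point are flagged. Metrics are MCC, precision,
recall and PR-AUC (step-wise non-interpolated curve; constant scores give
the prevalence by convention). Uncertainty uses a stratified bootstrap:
5000 resamples drawn with replacement within predicted-risk strata,
preserving the high-/low-risk ratio, summarized by the bootstrap mean and
percentile 2.5/97.5 bounds (the percentile method is a design choice; the
interval construction behind the published tables is not specified).
Survival analysis uses Kaplan-Meier curves per risk group, the two-group
log-rank test, and a single-covariate Cox proportional-hazards fit for the
hazard ratio. `confidence_strata_benchmark()` pairs the high-confidence
subset with the full set — the analysis showing that confidence identifies
trustworthy predictions — and `missingness_vs_correctness()` compares
per-patient missing-feature rates between correctly and incorrectly
predicted patients with a rank-based two-sample test.

Patients between the confidence cutoffs have no published dichotomization
rule for "all predictions" analyses; this package calls them high-risk at
a soft-vote of 0.5, and weights outcome-specific learners equally in the
composite confidence, as the averaging description implies.

## Monitoring

`schedule_windows()` partitions the prediction log into consecutive
91-day windows (a trailing remainder shorter than one window is merged
into the last window, which is flagged partial); a patient matures when
follow-up covers the 730-day horizon, in the window containing
prediction day + 730. `evaluate_window()` compares each window to the
training-era reference: numeric inputs by population-stability index (PSI)
over reference deciles plus a two-sample Kolmogorov-Smirnov test,
categoricals by PSI over categories, the confidence distribution and
risk-factor frequencies likewise. Empty PSI cells receive a 0.5
pseudo-count, keeping the index finite, nonnegative and zero exactly on
identical binned distributions. A variable is flagged at PSI > 0.2 or KS
p below 0.01/m (Bonferroni over the m monitored variables); performance
(MCC, precision, recall) is computed only on matured patients, with a
window lacking matured outcomes reported as "immature". Under the null,
the family-wise alarm rate stays below 5%; a 2-standard-deviation mean
shift at 1000 patients/window is detected essentially always. The
upstream system's own metric choices are not public; these defaults are
documented and configurable.

## Numerical and design choices

- Thresholds: `derive_thresholds()` picks the smallest observed value whose
  upper tail fraction does not exceed the target (and symmetrically from
  below), so achieved fractions are within 1/n of the targets.
- Ensemble hyperparameters (shallow trees of depth ≤ 4, 200 trees for
  forest families, elastic-net mixing 0.5, bag fraction 0.5) are
  deliberately modest defaults, all overridable via
  `ensemble_config(hyperparameters =)`; determinism comes from per-learner
  seeds derived from one configuration seed.
- Serialization uses a single RDS archive (boosted learners stored as raw
  byte blobs), the R-native equivalent of a manifest-plus-blobs archive;
  two fits under the same seed serialize bit-identically.
- Degenerate inputs are explicit: undefined metric denominators yield `NA`,
  an empty high-confidence subset is reported rather than raised, a
  single-class training target raises an error naming the target.

## Problem sizes used by the test and acceptance suites

The package's own checks run at desk scale, chosen to make the tested
properties statistically decisive: generator rate recovery at n = 5000;
missingness recovery at n = 2000–10000; the confidence-stratification
property on 10 independent train/test pairs of 350 + 350 patients with the
full 28-learner ensemble and a reduced 6-variable laboratory panel for the
remaining integration tests; 20 seeded harmonization fixtures of 15
patients; monitoring size over 200 null windows and power over 60 shifted
windows of 1000 patients; Cox recovery over 100 simulations of 1000
patients. The worked benchmark example recomputes metrics from the
published high-confidence confusion matrix (TP 43, FP 17, TN 71, FN 14)
directly and under the 5000-replicate stratified bootstrap.

## Known limitations

The registry approximates rather than replicates the production feature
set; learned parameters of the original deployed model are not
reproducible from public information, so all performance statements on
synthetic cohorts are directional. The generator's independence
assumptions (across variables and over time) understate the structure of
real EHR data. Survival benchmarking is single-event right-censored; no
competing-risks or multi-state estimators are provided, and calibration
beyond the threshold shift is out of scope.
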