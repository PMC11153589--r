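# Benchmarking: outcome labelling, metrics, bootstrap, survival,
# missingness profiling, comparator coverage.

test_that("outcome labelling implements the 2-year censoring rule", {
  ids <- c("A", "B", "C", "D", "E")
  co <- manual_cohort(ids, outcomes = data.frame(
    patient_id = ids,
    event_type = c("infection", "none", "none", "treatment", "infection"),
    event_day = c(92L + 100L, NA, NA, 92L + 800L, 50L),
    followup_end_day = c(92L + 600L, 92L + 400L, 92L + 731L, 92L + 900L, 500L),
    stringsAsFactors = FALSE))
  lab <- label_outcomes(co)
  expect_identical(lab$label, c("positive", "excluded", "negative",
                                "negative", "excluded"))
  # short-followup patient is censored at 400 d for survival use
  expect_equal(lab$time[2], 400)
  expect_false(lab$event[2])
  expect_identical(lab$reason[2], "followup_shorter_than_horizon")
  # event before the prediction point is flagged
  expect_identical(lab$reason[5], "event_before_prediction_point")
  # boundary: follow-up of exactly the horizon is evaluable
  co2 <- manual_cohort("F", outcomes = data.frame(
    patient_id = "F", event_type = "none", event_day = NA_integer_,
    followup_end_day = 92L + 730L, stringsAsFactors = FALSE))
  expect_identical(label_outcomes(co2)$label, "negative")
})

test_that("classification metrics match their closed forms", {
  cm <- c(TP = 43, FP = 17, TN = 71, FN = 14)
  m <- classification_metrics(cm)
  expect_equal(m$recall, 43 / 57)
  expect_equal(m$precision, 43 / 60)
  expect_equal(m$mcc, (43 * 71 - 17 * 14) / sqrt(60 * 57 * 88 * 85))
  perfect <- classification_metrics(c(TP = 5, FP = 0, TN = 9, FN = 0))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  # undefined denominators are NA, not errors
  expect_true(is.na(classification_metrics(c(TP = 0, FP = 0, TN = 3,
                                             FN = 0))$precision))
})

test_that("excluded patients never enter the confusion matrix", {
  cm <- confusion_matrix(c("high", "low", "high"),
                         c("positive", "negative", "excluded"))
  expect_equal(sum(cm), 2)
})

test_that("PR-AUC follows the step-wise curve and its conventions", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.7, 0.2, 0.1), c(1, 1, 1, 0, 0)), 1.0)
  expect_equal(pr_auc(rep(0.5, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  expect_true(is.na(pr_auc(runif(5), rep(1, 5))))
  # exhaustive threshold-enumeration oracle on a 6-point toy problem
  s <- c(0.9, 0.8, 0.6, 0.55, 0.3, 0.2)
  y <- c(1, 0, 1, 1, 0, 1)
  oracle <- local({
    thr <- sort(unique(s), decreasing = TRUE)
    rec <- pre <- numeric(0)
    for (t in thr) {
      tp <- sum(s >= t & y == 1); fp <- sum(s >= t & y == 0)
      rec <- c(rec, tp / sum(y)); pre <- c(pre, tp / (tp + fp))
    }
    sum(diff(c(0, rec)) * pre)
  })
  expect_equal(pr_auc(s, y), oracle)
})

test_that("stratified bootstrap preserves strata and degenerates correctly", {
  df <- data.frame(patient_id = sprintf("P%02d", 1:30),
                   risk_call = rep(c("high", "low"), c(10, 20)),
                   label = rep(c("positive", "negative"), c(10, 20)),
                   confidence = rep(c(0.9, 0.1), c(10, 20)))
  # all patients in a stratum identical -> zero-width CI
  bs <- bootstrap_summary(df, "precision", bootstrap_config(replicates = 200))
  expect_equal(bs$ci[1], bs$ci[2])
  expect_equal(bs$point, 1)
  expect_equal(bootstrap_config()$replicates, 5000L)
  expect_error(bootstrap_summary(df[df$risk_call == "high", ][0, ], "mcc"),
               "stratum")
})

test_that("bootstrap mean of a linear statistic converges to the point estimate", {
  set.seed(10)
  df <- data.frame(patient_id = sprintf("P%02d", 1:50),
                   risk_call = sample(c("high", "low"), 50, TRUE),
                   label = sample(c("positive", "negative"), 50, TRUE))
  frac_pos <- function(d) mean(d$label == "positive")
  bs <- bootstrap_summary(df, frac_pos,
                          bootstrap_config(replicates = 50000, seed = 3))
  expect_lt(abs(bs$mean - bs$point), 0.002)
})

test_that("bootstrap percentile CIs cover a binomial proportion at the nominal rate", {
  p_true <- 0.3; n <- 200
  hits <- vapply(1:120, function(s) {
    set.seed(s)
    y <- rbinom(n, 1, p_true)
    df <- data.frame(y = y)
    bs <- bootstrap_summary(df, function(d) mean(d$y),
                            bootstrap_config(replicates = 400, stratified = FALSE,
                                             seed = s))
    bs$ci[1] <= p_true && p_true <= bs$ci[2]
  }, logical(1))
  expect_gt(mean(hits), 0.90)
})

test_that("identical risk groups give a null survival contrast", {
  ids <- sprintf("P%02d", 1:40)
  times <- rep(c(100, 200, 300, 400, 500), 8)
  events <- rep(c(TRUE, FALSE), 20)
  pred <- data.frame(patient_id = ids,
                     risk_call = rep(c("high", "low"), each = 20),
                     confidence = 0.5)
  lab <- data.frame(patient_id = ids, label = "positive", time = times,
                    event = events, reason = NA_character_)
  sr <- survival_benchmark(pred, lab)
  expect_equal(sr$hr, 1, tolerance = 1e-6)
  expect_gt(sr$logrank_p, 0.99)
})

test_that("without censoring the KM estimate equals the empirical survival fraction", {
  ids <- sprintf("P%02d", 1:30)
  set.seed(8)
  times <- sample(50:900, 30)
  pred <- data.frame(patient_id = ids, risk_call = "high", confidence = 0.9)
  lab <- data.frame(patient_id = ids, label = "positive", time = times,
                    event = TRUE, reason = NA_character_)
  sr <- survival_benchmark(pred, lab)
  km <- summary(sr$km)
  expect_equal(km$surv, vapply(km$time, function(t) mean(times > t), numeric(1)))
})

test_that("missingness profiling matches a by-hand computation", {
  labs <- data.frame(
    patient_id = c("A", "A", "B"), day = c(92L - 365L, 92L, 92L - 730L),
    variable = c("hemoglobin", "leukocytes", "hemoglobin"),
    value = 1, unit = "u", stringsAsFactors = FALSE)
  co <- manual_cohort(c("A", "B", "C"), labs = labs,
                      cultures = data.frame(patient_id = "B", day = 10L))
  pm <- profile_missingness(co)
  # availability: A has 2/2 labs, B 1/2, C 0/2
  expect_equal(pm$lab_availability, mean(c(1, 0.5, 0)))
  # depth per lab: hemoglobin mean(365, 730)/365.25; leukocytes 0
  expect_equal(pm$historical_depth_years,
               mean(c(mean(c(365, 730)) / 365.25, 0 / 365.25)))
  expect_equal(pm$culture_availability, 1 / 3)
  expect_equal(unname(pm$baseline_missingness["binet"]), 0)
})

test_that("preset missingness propagates to the profile", {
  co <- generate_cohort(cohort_preset("deployment", n_patients = 2000,
                                      seed = 17, lab_panel = small_panel(1)))
  pm <- profile_missingness(co)
  expect_lt(abs(pm$baseline_missingness[["binet"]] - 0.722), 0.03)
  expect_lt(abs(pm$baseline_missingness[["ighv"]] - 0.911), 0.02)
  expect_equal(pm$baseline_missingness[["ecog"]], 1.0)
})

test_that("missing-rate comparison is null-centred for identical groups and detects targeted missingness", {
  ids <- sprintf("P%03d", 1:200)
  pred <- data.frame(patient_id = ids,
                     risk_call = rep(c("high", "low"), each = 100),
                     confidence = 0.5)
  lab <- data.frame(patient_id = ids,
                    label = rep(c("positive", "negative", "positive",
                                  "negative"), each = 50),
                    time = 100, event = TRUE, reason = NA_character_)
  set.seed(5)
  mr <- stats::setNames(runif(200, 0.1, 0.3), ids)
  mc <- missingness_vs_correctness(pred, lab, mr)
  expect_gt(mc$predicted_high$p_value, 0.05)
  # concentrate missingness on true positives -> detectable difference
  mr2 <- mr
  mr2[1:50] <- mr2[1:50] + 0.5
  mc2 <- missingness_vs_correctness(pred, lab, mr2)
  expect_lt(mc2$predicted_high$p_value, 0.01)
  # empty group is a notice, not an error
  mc3 <- missingness_vs_correctness(pred[1:50, ], lab[1:50, ], mr)
  expect_match(mc3$predicted_low$note, "empty")
})

test_that("comparator coverage requires its inputs and collapses under missingness", {
  co <- small_cohort(n = 60, seed = 41)
  co$baseline$binet <- "A"; co$baseline$ighv <- "mutated"
  co$baseline$b2m_high <- "no"; co$baseline$fish <- "normal"
  cov <- coverage_comparison(co)
  expect_equal(cov$ensemble_coverage, 1.0)
  expect_equal(cov$comparator_coverage, 1.0)
  # brute-force AND of availability indicators
  co2 <- inject_missingness(co, c(binet = 0.5, ighv = 0.6, fish = 0.3))
  sc <- score_comparator(co2)
  brute <- with(co2$baseline, binet != "unknown" & ighv != "unknown" &
                  b2m_high != "unknown" & fish != "unknown" &
                  age65 != "unknown")
  expect_identical(sc$covered, brute)
  expect_equal(coverage_comparison(co2)$comparator_coverage, mean(brute))
  # impute mode waives Binet and IGHV only
  sc_imp <- score_comparator(co2, comparator_score(mode = "impute_binet_ighv"))
  expect_identical(sc_imp$covered,
                   with(co2$baseline, b2m_high != "unknown" &
                          fish != "unknown" & age65 != "unknown"))
})

test_that("comparator coverage is monotone nonincreasing in marginal missingness", {
  co <- small_cohort(n = 150, seed = 43)
  probs <- seq(0, 0.9, by = 0.3)
  covs <- vapply(probs, function(p) {
    set.seed(99)  # same mask randomness, increasing marginal probability
    coverage_comparison(inject_missingness(co, c(binet = p, ighv = p)))$comparator_coverage
  }, numeric(1))
  expect_true(all(diff(covs) <= 1e-12))
})

test_that("comparator scores reproduce the weighted index", {
  co <- manual_cohort("X", baseline_overrides = list(
    age65 = "yes", binet = "C", b2m_high = "yes", ighv = "unmutated",
    fish = "del17p"))
  sc <- score_comparator(co)
  expect_equal(sc$score, 1 + 1 + 2 + 2 + 4)
  expect_identical(sc$category, "very_high")
  co2 <- manual_cohort("Y")  # all favourable
  expect_equal(score_comparator(co2)$score, 0)
  expect_identical(score_comparator(co2)$category, "low")
})

test_that("confidence-stratified benchmarking with degenerate thresholds collapses to one report", {
  fx <- fit_small_model()
  pred <- predict(fx$model, fx$features)
  lab <- label_outcomes(fx$cohort)
  rep <- confidence_strata_benchmark(
    pred, lab, confidence_thresholds(t_high = 1e-9, t_low = 0),
    bootstrap_config(replicates = 100, seed = 2))
  expect_equal(rep$high_confidence$n, rep$all$n)
  expect_equal(rep$high_confidence$metrics$mcc$point,
               rep$all$metrics$mcc$point)
  expect_equal(rep$high_conf_fraction, 1.0)
})
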