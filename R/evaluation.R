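# Benchmarking machinery: outcome labelling with the 2-year censoring rule,
# classification metrics (MCC, precision, recall, PR-AUC) with stratified
# bootstrap confidence intervals, confidence-stratified comparison,
# Kaplan-Meier / log-rank / Cox survival summaries, missingness profiling,
# and prediction-coverage comparison against a five-variable complete-case
# prognostic index (CLL-IPI-style comparator).

#' Label 2-year composite outcomes at the prediction point
#'
#' Positive: composite first event (infection or treatment) within the
#' horizon of the prediction point. Negative: event-free with follow-up of at
#' least the horizon. Excluded: event-free with follow-up shorter than the
#' horizon (kept with censor time for survival analysis), or an event dated
#' before the prediction point (flagged). `time` and `event` give the
#' survival representation (days from prediction point, right-censored at
#' end of follow-up).
#'
#' @param cohort an `ehr_cohort`.
#' @param policy a [prediction_point_policy()].
#' @return data.frame of class `outcome_labels`: `patient_id`, `label`
#'   (positive/negative/excluded), `time`, `event`, `reason`.
#' @export
label_outcomes <- function(cohort, policy = prediction_point_policy()) {
  oc <- cohort$outcomes
  if (is.null(oc) || nrow(oc) == 0L) stop_config("cohort has no outcome table")
  pp <- prediction_points(cohort, policy$offset_days_from_diagnosis)[oc$patient_id]
  H <- policy$outcome_horizon_days
  has_event <- oc$event_type != "none" & !is.na(oc$event_day)
  t_event <- ifelse(has_event, oc$event_day - pp, oc$followup_end_day - pp)
  label <- rep("excluded", nrow(oc))
  reason <- rep(NA_character_, nrow(oc))
  pre_pp <- has_event & oc$event_day <= pp
  label[pre_pp] <- "excluded"
  reason[pre_pp] <- "event_before_prediction_point"
  pos <- has_event & !pre_pp & (oc$event_day - pp) <= H
  label[pos] <- "positive"
  neg <- !pos & !pre_pp & pmin(ifelse(has_event, oc$event_day, Inf),
                               oc$followup_end_day) - pp >= H
  # event-free at the horizon with adequate follow-up (includes events
  # occurring after the horizon)
  label[neg & (!has_event | (oc$event_day - pp) > H)] <- "negative"
  short <- label == "excluded" & !pre_pp
  reason[short] <- "followup_shorter_than_horizon"
  out <- data.frame(patient_id = oc$patient_id, label = label,
                    time = pmax(as.numeric(t_event), 0),
                    event = has_event & !pre_pp,
                    reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("outcome_labels", "data.frame")
  out
}

#' Confusion matrix of risk calls against outcome labels
#'
#' Excluded patients never enter the confusion matrix.
#' @param risk_call character vector, "high"/"low".
#' @param label character vector, "positive"/"negative"/"excluded".
#' @return named integer vector (TP, FP, TN, FN) of class `confusion_matrix`.
#' @export
confusion_matrix <- function(risk_call, label) {
  keep <- label %in% c("positive", "negative")
  rc <- risk_call[keep]; lb <- label[keep]
  structure(c(TP = sum(rc == "high" & lb == "positive"),
              FP = sum(rc == "high" & lb == "negative"),
              TN = sum(rc == "low" & lb == "negative"),
              FN = sum(rc == "low" & lb == "positive")),
            class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`;
#' precision `TP/(TP+FP)`; recall `TP/(TP+FN)`. Undefined denominators are
#' reported as `NA` rather than raising.
#'
#' @param cm confusion matrix (named vector with TP, FP, TN, FN).
#' @return list with `mcc`, `precision`, `recall`.
#' @export
classification_metrics <- function(cm) {
  tp <- as.numeric(cm[["TP"]]); fp <- as.numeric(cm[["FP"]])
  tn <- as.numeric(cm[["TN"]]); fn <- as.numeric(cm[["FN"]])
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(mcc = if (denom > 0) (tp * tn - fp * fn) / denom else NA_real_,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) curve over all observed score thresholds:
#' the area is the sum of recall increments times the precision at each
#' threshold. With constant scores the curve collapses to a single point and
#' the area equals the prevalence (documented convention).
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels logical or 0/1 vector of true classes.
#' @return PR-AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
pr_auc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  npos <- sum(y == 1)
  if (npos == 0L || npos == length(y)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  # evaluate at each distinct threshold (groups of tied scores move together)
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]
  k <- seq_along(y)[last]
  recall <- tp / npos
  precision <- tp / k
  sum(diff(c(0, recall)) * precision)
}

#' Bootstrap configuration
#'
#' @param replicates number of bootstrap cohorts (default 5000).
#' @param stratified resample within predicted-risk strata, preserving the
#'   original high-risk to low-risk patient ratio (default TRUE)?
#' @param seed integer seed.
#' @return object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(replicates = 5000L, stratified = TRUE, seed = 1L) {
  if (replicates < 1L) stop_config("replicates must be >= 1")
  structure(list(replicates = as.integer(replicates), stratified = stratified,
                 seed = as.integer(seed)), class = "bootstrap_config")
}

builtin_metric <- function(name) {
  switch(name,
    mcc = function(df) classification_metrics(
      confusion_matrix(df$risk_call, df$label))$mcc,
    precision = function(df) classification_metrics(
      confusion_matrix(df$risk_call, df$label))$precision,
    recall = function(df) classification_metrics(
      confusion_matrix(df$risk_call, df$label))$recall,
    pr_auc = function(df) pr_auc(df$confidence, df$label == "positive"),
    stop_config("unknown metric '%s'", name))
}

#' Stratified bootstrap mean and percentile 95% CI of a metric
#'
#' Resamples patients with replacement within predicted-risk strata
#' (preserving stratum sizes), recomputes the metric per bootstrap cohort,
#' and reports the bootstrap mean with percentile 2.5/97.5 bounds.
#'
#' @param data per-patient data.frame with at least `risk_call` and `label`
#'   columns (plus `confidence` for `pr_auc`).
#' @param metric a metric name (`"mcc"`, `"precision"`, `"recall"`,
#'   `"pr_auc"`) or a function `data.frame -> numeric`.
#' @param config a [bootstrap_config()].
#' @return list with `point`, `mean`, `ci` (length 2), `replicates`.
#' @export
bootstrap_summary <- function(data, metric, config = bootstrap_config()) {
  fn <- if (is.function(metric)) metric else builtin_metric(metric)
  strata <- if (isTRUE(config$stratified)) data$risk_call else rep("all", nrow(data))
  idx_by <- split(seq_len(nrow(data)), strata)
  if (!length(idx_by) || any(lengths(idx_by) == 0L))
    stop_config("empty bootstrap stratum")
  point <- fn(data)
  vals <- with_seed(config$seed, {
    vapply(seq_len(config$replicates), function(b) {
      take <- unlist(lapply(idx_by, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]),
        use.names = FALSE)
      fn(data[take, , drop = FALSE])
    }, numeric(1))
  })
  list(point = point, mean = mean(vals, na.rm = TRUE),
       ci = unname(stats::quantile(vals, c(0.025, 0.975), na.rm = TRUE)),
       replicates = config$replicates)
}

#' Benchmark high-confidence predictions against all predictions
#'
#' Computes classification metrics with stratified bootstrap CIs on (i) the
#' high-confidence subset (band != low_confidence) and (ii) all evaluable
#' patients, plus the high-confidence fraction — the analysis that shows
#' whether predictive confidence identifies trustworthy predictions.
#'
#' @param predictions an `ensemble_prediction` data.frame.
#' @param labels an `outcome_labels` data.frame.
#' @param thresholds a [confidence_thresholds()]; bands are recomputed from
#'   it so a threshold sweep needs no re-prediction.
#' @param config a [bootstrap_config()].
#' @param metrics metric names to bootstrap.
#' @return list of class `benchmark_report`: `high_confidence`, `all`
#'   (each: n, confusion matrix, per-metric bootstrap summaries),
#'   `high_conf_fraction`.
#' @export
confidence_strata_benchmark <- function(predictions, labels,
                                        thresholds = confidence_thresholds(),
                                        config = bootstrap_config(),
                                        metrics = c("mcc", "precision",
                                                    "recall", "pr_auc")) {
  df <- merge(as.data.frame(predictions), as.data.frame(labels),
              by = "patient_id")
  df$band <- confidence_band(df$confidence, thresholds)
  df <- df[df$label %in% c("positive", "negative"), , drop = FALSE]
  eval_set <- function(sub) {
    if (nrow(sub) == 0L)
      return(list(n = 0L, cm = NULL, metrics = NULL, note = "empty subset"))
    cm <- confusion_matrix(sub$risk_call, sub$label)
    ms <- lapply(stats::setNames(metrics, metrics), function(m)
      tryCatch(bootstrap_summary(sub, m, config),
               ehrisk_config_error = function(e) list(point = NA_real_,
                                                      mean = NA_real_,
                                                      ci = c(NA_real_, NA_real_),
                                                      note = conditionMessage(e))))
    list(n = nrow(sub), cm = cm, metrics = ms)
  }
  hc <- df[df$band != "low_confidence", , drop = FALSE]
  structure(list(high_confidence = eval_set(hc), all = eval_set(df),
                 high_conf_fraction = mean(df$band != "low_confidence"),
                 thresholds = thresholds),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  show <- function(nm, s) {
    cat(sprintf("%s (n = %d):\n", nm, s$n))
    if (is.null(s$metrics)) { cat("  (empty)\n"); return(invisible()) }
    for (m in names(s$metrics)) {
      b <- s$metrics[[m]]
      cat(sprintf("  %-9s %.3f (bootstrap mean %.3f, 95%% CI %.3f-%.3f)\n",
                  m, b$point, b$mean, b$ci[1], b$ci[2]))
    }
  }
  show("High-confidence predictions", x$high_confidence)
  show("All predictions", x$all)
  cat(sprintf("High-confidence fraction: %.1f%%\n", 100 * x$high_conf_fraction))
  invisible(x)
}

#' Survival benchmark of predicted risk groups
#'
#' Kaplan-Meier curves per predicted risk group (right-censored; excluded
#' patients contribute censored times), two-group log-rank test, and the
#' hazard ratio from a single-covariate Cox proportional-hazards fit on the
#' risk call.
#'
#' @param predictions an `ensemble_prediction` data.frame.
#' @param labels an `outcome_labels` data.frame (censoring included).
#' @return list of class `survival_report`: `km` (a `survfit`), `logrank_p`,
#'   `hr`, `hr_ci`, `n`, `events`.
#' @export
survival_benchmark <- function(predictions, labels) {
  df <- merge(as.data.frame(predictions), as.data.frame(labels),
              by = "patient_id")
  df <- df[is.na(df$reason) | df$reason != "event_before_prediction_point", ,
           drop = FALSE]
  df$time <- pmax(df$time, 0.5)  # guard zero times for Surv
  if (sum(df$event) < 1L) {
    return(structure(list(km = NULL, logrank_p = NA_real_, hr = NA_real_,
                          hr_ci = c(NA_real_, NA_real_), n = nrow(df),
                          events = 0L, note = "no events"),
                     class = "survival_report"))
  }
  surv <- survival::Surv(df$time, df$event)
  group <- factor(df$risk_call, levels = c("low", "high"))
  km <- survival::survfit(surv ~ group)
  logrank_p <- if (nlevels(droplevels(group)) == 2L) {
    sd <- survival::survdiff(surv ~ group)
    stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  } else NA_real_
  hr <- NA_real_; hr_ci <- c(NA_real_, NA_real_)
  if (nlevels(droplevels(group)) == 2L) {
    cx <- survival::coxph(surv ~ group)
    hr <- unname(exp(stats::coef(cx)))
    hr_ci <- unname(exp(stats::confint(cx)[1, ]))
  }
  structure(list(km = km, logrank_p = logrank_p, hr = hr, hr_ci = hr_ci,
                 n = nrow(df), events = sum(df$event)),
            class = "survival_report")
}

#' @export
print.survival_report <- function(x, ...) {
  cat(sprintf("Survival benchmark: n = %d, events = %d\n", x$n, x$events))
  cat(sprintf("High- vs low-risk HR = %.2f (95%% CI %.2f-%.2f), log-rank p = %.3g\n",
              x$hr, x$hr_ci[1], x$hr_ci[2], x$logrank_p))
  invisible(x)
}

#' Plot Kaplan-Meier curves from a survival report
#' @param x a `survival_report`.
#' @param ... passed to `plot.survfit`.
#' @export
plot.survival_report <- function(x, ...) {
  if (is.null(x$km)) stop_config("no events; nothing to plot")
  plot(x$km, col = c("goldenrod", "steelblue"), lwd = 2,
       xlab = "Days from prediction point",
       ylab = "Event-free survival", ...)
  graphics::legend("bottomleft", c("low risk", "high risk"),
                   col = c("goldenrod", "steelblue"), lwd = 2, bty = "n")
  invisible(x)
}

#' Profile structured-data availability of a cohort
#'
#' Computes, up to the prediction point only: (a) mean per-patient fraction
#' of panel laboratory variables with at least one event, (b) mean
#' historical depth (mean over laboratory variables of the mean over
#' patients of years from the earliest test to the prediction point),
#' (c) fraction of patients with at least one blood-culture event, and
#' (d) per-variable baseline missingness.
#'
#' @param cohort an `ehr_cohort`.
#' @param policy a [prediction_point_policy()].
#' @return list of class `missingness_profile`.
#' @export
profile_missingness <- function(cohort, policy = prediction_point_policy()) {
  n <- nrow(cohort$baseline)
  if (n == 0L) stop_config("cohort is empty")
  ids <- cohort$baseline$patient_id
  pp <- prediction_points(cohort, policy$offset_days_from_diagnosis)
  panel_vars <- unique(cohort$spec$lab_panel$variable)
  labs <- cohort$labs
  rel <- if (nrow(labs)) pp[labs$patient_id] - labs$day else numeric(0)
  pre <- labs[rel >= 0, , drop = FALSE]
  rel <- rel[rel >= 0]
  avail <- matrix(FALSE, n, length(panel_vars), dimnames = list(ids, panel_vars))
  depth <- matrix(NA_real_, n, length(panel_vars), dimnames = list(ids, panel_vars))
  if (nrow(pre)) {
    for (v in panel_vars) {
      sel <- pre$variable == v
      if (!any(sel)) next
      g <- factor(match(pre$patient_id[sel], ids), levels = seq_len(n))
      eldest <- as.numeric(tapply(rel[sel], g, max))
      avail[, v] <- !is.na(eldest)
      depth[, v] <- eldest / 365.25
    }
  }
  cult_rel <- if (nrow(cohort$cultures))
    pp[cohort$cultures$patient_id] - cohort$cultures$day else numeric(0)
  cult_pat <- unique(cohort$cultures$patient_id[cult_rel >= 0])
  base_miss <- vapply(names(baseline_variables()), function(v)
    mean(cohort$baseline[[v]] == "unknown"), numeric(1))
  structure(list(
    lab_availability = mean(rowMeans(avail)),
    lab_availability_by_variable = colMeans(avail),
    historical_depth_years = mean(colMeans(depth, na.rm = TRUE), na.rm = TRUE),
    culture_availability = length(cult_pat) / n,
    baseline_missingness = base_miss, n = n),
    class = "missingness_profile")
}

#' @export
print.missingness_profile <- function(x, ...) {
  cat(sprintf("Missingness profile (n = %d)\n", x$n))
  cat(sprintf("  Lab availability (mean fraction of panel): %.3f\n",
              x$lab_availability))
  cat(sprintf("  Historical depth: %.2f years\n", x$historical_depth_years))
  cat(sprintf("  Blood-culture availability: %.3f\n", x$culture_availability))
  cat("  Baseline missingness:\n")
  for (v in names(x$baseline_missingness))
    cat(sprintf("    %-9s %.3f\n", v, x$baseline_missingness[[v]]))
  invisible(x)
}

#' Compare feature missing rates between correct and incorrect predictions
#'
#' Within each predicted-risk class, compares the per-patient feature missing
#' rate of correctly vs incorrectly predicted patients (TP vs FP, TN vs FN)
#' with a rank-based two-sample (Wilcoxon) test. Comparisons with an empty
#' group are skipped with a notice.
#'
#' @param predictions an `ensemble_prediction` data.frame.
#' @param labels an `outcome_labels` data.frame.
#' @param missing_rates named per-patient missing-rate vector
#'   ([patient_missing_rate()]).
#' @return list of class `missingness_correctness` with one entry per
#'   comparison: group summaries, `statistic`, `p_value` (or `note`).
#' @export
missingness_vs_correctness <- function(predictions, labels, missing_rates) {
  df <- merge(as.data.frame(predictions), as.data.frame(labels),
              by = "patient_id")
  df <- df[df$label %in% c("positive", "negative"), , drop = FALSE]
  df$missing_rate <- missing_rates[df$patient_id]
  df$correct <- (df$risk_call == "high") == (df$label == "positive")
  one <- function(sub, name_ok, name_bad) {
    a <- sub$missing_rate[sub$correct]
    b <- sub$missing_rate[!sub$correct]
    summ <- function(v) list(n = length(v), mean = mean(v),
                             median = stats::median(v))
    if (!length(a) || !length(b))
      return(list(groups = list(summ(a), summ(b)),
                  note = "empty group; comparison skipped"))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    list(groups = stats::setNames(list(summ(a), summ(b)),
                                  c(name_ok, name_bad)),
         statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  structure(list(
    predicted_high = one(df[df$risk_call == "high", ], "TP", "FP"),
    predicted_low = one(df[df$risk_call == "low", ], "TN", "FN")),
    class = "missingness_correctness")
}

#' Five-variable comparator prognostic index (CLL-IPI-style)
#'
#' Integer-weighted index over age > 65 (1), Binet stage B/C (1),
#' beta-2-microglobulin > 4 mg/L (2), IGHV unmutated (2) and del(17p)/TP53
#' aberration (4), with risk categories 0-1 / 2-3 / 4-5 / 6-10. In
#' `complete_case` mode a score exists only when all five inputs are
#' available; `impute_binet_ighv` mode drops the Binet and IGHV requirement
#' (the two variables a deployment site can backfill) and requires the
#' remaining three.
#'
#' @param weights named integer weights for the five inputs.
#' @param breaks score cut points between categories.
#' @param mode `"complete_case"` or `"impute_binet_ighv"`.
#' @return object of class `comparator_score`.
#' @export
comparator_score <- function(weights = c(age65 = 1, binet = 1, b2m_high = 2,
                                         ighv = 2, del17p = 4),
                             breaks = c(2, 4, 6),
                             mode = c("complete_case", "impute_binet_ighv")) {
  mode <- match.arg(mode)
  structure(list(weights = weights, breaks = breaks, mode = mode),
            class = "comparator_score")
}

comparator_inputs <- function(baseline) {
  data.frame(
    age65 = baseline$age65 == "yes",
    binet = baseline$binet %in% c("B", "C"),
    b2m_high = baseline$b2m_high == "yes",
    ighv = baseline$ighv == "unmutated",
    del17p = baseline$fish == "del17p",
    avail_age65 = baseline$age65 != "unknown",
    avail_binet = baseline$binet != "unknown",
    avail_b2m_high = baseline$b2m_high != "unknown",
    avail_ighv = baseline$ighv != "unknown",
    avail_del17p = baseline$fish != "unknown")
}

#' Score the comparator index for a cohort
#'
#' @param cohort an `ehr_cohort`.
#' @param comparator a [comparator_score()].
#' @return data.frame with `patient_id`, `score` (NA where inputs required
#'   by the mode are missing), `category`, `covered` (logical).
#' @export
score_comparator <- function(cohort, comparator = comparator_score()) {
  ci <- comparator_inputs(cohort$baseline)
  req <- if (comparator$mode == "complete_case")
    c("age65", "binet", "b2m_high", "ighv", "del17p")
  else c("age65", "b2m_high", "del17p")
  covered <- Reduce(`&`, lapply(req, function(v) ci[[paste0("avail_", v)]]))
  w <- comparator$weights
  score <- as.numeric(as.matrix(ci[, names(w)]) %*% w)
  score[!covered] <- NA_real_
  category <- cut(score, breaks = c(-Inf, comparator$breaks - 0.5, Inf),
                  labels = c("low", "intermediate", "high", "very_high"))
  data.frame(patient_id = cohort$baseline$patient_id, score = score,
             category = as.character(category), covered = covered,
             stringsAsFactors = FALSE)
}

#' Prediction-coverage comparison: ensemble vs low-dimensional comparator
#'
#' The ensemble returns a prediction for every patient regardless of
#' missingness (coverage contractually 1); the comparator requires all of
#' its inputs, so its coverage collapses under structured-data missingness.
#'
#' @param cohort an `ehr_cohort`.
#' @param model a fitted `cll_ensemble`, an `ensemble_prediction` data.frame,
#'   or `NULL` (contractual coverage assumed).
#' @param comparator a [comparator_score()].
#' @param registry,policy used to featurize when `model` is a fitted
#'   ensemble.
#' @return list of class `coverage_report`: `ensemble_coverage`,
#'   `comparator_coverage`, `comparator_n`, `n`.
#' @export
coverage_comparison <- function(cohort, model = NULL,
                                comparator = comparator_score(),
                                registry = NULL,
                                policy = prediction_point_policy()) {
  n <- nrow(cohort$baseline)
  ens_cov <- if (inherits(model, "cll_ensemble")) {
    reg <- registry %||% model$registry
    fm <- extract_features(cohort, reg, policy)
    pred <- predict(model, fm)
    sum(!is.na(pred$confidence)) / n
  } else if (inherits(model, "data.frame")) {
    sum(cohort$baseline$patient_id %in% model$patient_id) / n
  } else 1.0
  sc <- score_comparator(cohort, comparator)
  structure(list(ensemble_coverage = ens_cov,
                 comparator_coverage = mean(sc$covered),
                 comparator_n = sum(sc$covered), n = n,
                 mode = comparator$mode),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Prediction coverage (n = %d): ensemble %.1f%%, comparator (%s) %.2f%% (%d/%d)\n",
              x$n, 100 * x$ensemble_coverage, x$mode,
              100 * x$comparator_coverage, x$comparator_n, x$n))
  invisible(x)
}

#' Export a benchmark report as JSON
#' @param report a `benchmark_report`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_benchmark_report <- function(report, path) {
  ser <- function(s) {
    if (is.null(s$metrics)) return(list(n = s$n, note = s$note))
    list(n = s$n, confusion = as.list(s$cm),
         metrics = lapply(s$metrics, function(b)
           list(point = b$point, mean = b$mean, ci = b$ci)))
  }
  jsonlite::write_json(list(high_confidence = ser(report$high_confidence),
                            all = ser(report$all),
                            high_conf_fraction = report$high_conf_fraction),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
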