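# Temporal feature engine: turns longitudinal patient records into the fixed
# width numeric matrix consumed by the ensemble, with the feature-level
# missingness layer made explicit -- counts encode absence as 0,
# days-since-latest encodes recency, value aggregates are NA on empty
# windows, and baseline categoricals are one-hot encoded with an explicit
# "unknown" indicator.

#' Prediction-point policy
#'
#' Fixes the temporal frame of the model: where the prediction point sits
#' relative to diagnosis, how far back features may look, and the outcome
#' horizon. Calendar phrases are pinned to integer days: 3 months = 92 days,
#' 7 years = 2557 days, 2 years = 730 days.
#'
#' @param offset_days_from_diagnosis days from diagnosis to the prediction
#'   point (default 92).
#' @param lookback_days maximum feature window length (default 2557); must be
#'   at least as long as every registry window.
#' @param outcome_horizon_days outcome horizon (default 730).
#' @return object of class `pp_policy`.
#' @export
prediction_point_policy <- function(offset_days_from_diagnosis = 92L,
                                    lookback_days = 2557L,
                                    outcome_horizon_days = 730L) {
  vals <- c(offset_days_from_diagnosis, lookback_days, outcome_horizon_days)
  if (any(vals <= 0)) stop_config("all policy day counts must be positive")
  structure(list(offset_days_from_diagnosis = as.integer(offset_days_from_diagnosis),
                 lookback_days = as.integer(lookback_days),
                 outcome_horizon_days = as.integer(outcome_horizon_days)),
            class = "pp_policy")
}

#' Default baseline one-hot vocabulary
#'
#' Levels for each baseline variable, always including `"unknown"` so that
#' missingness is an explicit indicator column.
#' @return named list of character level vectors.
#' @export
default_baseline_levels <- function() {
  lapply(baseline_variables(), function(l) c(l, "unknown"))
}

#' Build the default feature registry
#'
#' For each laboratory variable, emits `{min, median, count,
#' days_since_latest}` over a short and a long window; for blood cultures,
#' `{count, days_since_latest}` over 365- and 2557-day windows; for each
#' baseline variable, one indicator per level including `"unknown"`. The
#' registry approximates, at configurable scale, the design of a
#' 228-feature / 84-variable production feature set; an externally supplied
#' feature list can be passed to [extract_features()] instead.
#'
#' @param lab_panel data.frame with a `variable` column ([default_lab_panel()]).
#' @param baseline_levels named list of levels per baseline variable
#'   (default [default_baseline_levels()]); use `list()` for none.
#' @param lab_windows integer vector of lab window lengths in days.
#' @param lab_aggregators aggregators applied to each lab window.
#' @param culture_windows integer vector of culture window lengths (use
#'   `integer(0)` to omit culture features).
#' @return data.frame of class `feature_registry` with columns `feature_id`,
#'   `variable`, `window_days`, `aggregator`, `applies_to`, `level`.
#' @export
default_registry <- function(lab_panel,
                             baseline_levels = default_baseline_levels(),
                             lab_windows = c(92L, 2557L),
                             lab_aggregators = c("min", "median", "count",
                                                 "days_since_latest"),
                             culture_windows = c(365L, 2557L)) {
  if (is.null(lab_panel) || nrow(lab_panel) == 0L)
    stop_config("lab_panel must be nonempty")
  rows <- list()
  for (v in lab_panel$variable)
    for (w in lab_windows)
      for (a in lab_aggregators)
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = sprintf("%s_%s_%dd", v, a, w), variable = v,
          window_days = w, aggregator = a, applies_to = "lab",
          level = NA_character_, stringsAsFactors = FALSE)
  for (w in culture_windows)
    for (a in c("count", "days_since_latest"))
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = sprintf("blood_culture_%s_%dd", a, w),
        variable = "blood_culture", window_days = w, aggregator = a,
        applies_to = "culture", level = NA_character_, stringsAsFactors = FALSE)
  for (v in names(baseline_levels))
    for (lev in baseline_levels[[v]])
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = sprintf("%s.%s", v, lev), variable = v,
        window_days = NA_integer_, aggregator = "onehot",
        applies_to = "baseline", level = lev, stringsAsFactors = FALSE)
  reg <- do.call(rbind, rows)
  if (anyDuplicated(reg$feature_id)) stop_config("duplicate feature ids in registry")
  class(reg) <- c("feature_registry", "data.frame")
  reg
}

VALUE_AGGREGATORS <- c("min", "max", "median", "mean", "latest")

aggregate_window <- function(rel, value, group, n, aggregator) {
  # rel: days before the prediction point (>= 0, <= window) for qualifying
  # events; group: patient index 1..n. Value aggregators are NA on empty
  # windows; count encodes absence as 0.
  if (aggregator == "count") return(tabulate(group, nbins = n))
  out <- rep(NA_real_, n)
  if (!length(group)) return(out)
  if (aggregator == "days_since_latest") {
    agg <- tapply(rel, factor(group, levels = seq_len(n)), min)
    return(as.numeric(agg))
  }
  f <- factor(group, levels = seq_len(n))
  out <- switch(aggregator,
    min    = as.numeric(tapply(value, f, min)),
    max    = as.numeric(tapply(value, f, max)),
    median = as.numeric(tapply(value, f, stats::median)),
    mean   = as.numeric(tapply(value, f, mean)),
    latest = as.numeric(tapply(seq_along(rel), f, function(i) {
      # ties at the identical latest timestamp aggregate by mean
      mean(value[i][rel[i] == min(rel[i])])
    })),
    stop_config("unknown aggregator '%s'", aggregator))
  out
}

#' Extract the feature matrix at the prediction point
#'
#' Only events with timestamp within the closed window
#' `[prediction point - window, prediction point]` contribute; events after
#' the prediction point never do. Counts are 0 on empty windows (absence is
#' informative), `days_since_latest` and value aggregators are `NA` when no
#' qualifying event exists, and each baseline variable contributes a one-hot
#' block in which exactly one indicator (possibly `"unknown"`) is 1.
#'
#' @param cohort an `ehr_cohort`.
#' @param registry a `feature_registry` ([default_registry()]).
#' @param policy a [prediction_point_policy()].
#' @return object of class `feature_matrix`: list with `x` (patients x
#'   features numeric matrix, `NA` = missing), `registry`, `policy`,
#'   `missing_rate` (per-patient fraction of missing features).
#' @export
extract_features <- function(cohort, registry, policy = prediction_point_policy()) {
  stopifnot(inherits(cohort, "ehr_cohort"), inherits(policy, "pp_policy"))
  if (nrow(registry) == 0L) stop_config("registry must be nonempty")
  wmax <- suppressWarnings(max(registry$window_days, na.rm = TRUE))
  if (is.finite(wmax) && wmax > policy$lookback_days)
    stop_config("policy lookback (%d d) shorter than longest feature window (%d d)",
                policy$lookback_days, wmax)
  known <- c(unique(cohort$spec$lab_panel$variable), unique(cohort$labs$variable),
             "blood_culture", names(baseline_variables()))
  bad <- setdiff(registry$variable, known)
  if (length(bad))
    stop_config("registry references unknown variable(s): %s",
                paste(bad, collapse = ", "))

  ids <- cohort$baseline$patient_id
  n <- length(ids)
  pp <- cohort$baseline$diagnosis_day + policy$offset_days_from_diagnosis
  x <- matrix(NA_real_, n, nrow(registry),
              dimnames = list(ids, registry$feature_id))

  labs <- cohort$labs
  lab_rel <- if (nrow(labs)) pp[match(labs$patient_id, ids)] - labs$day else numeric(0)
  cult <- cohort$cultures
  cult_rel <- if (nrow(cult)) pp[match(cult$patient_id, ids)] - cult$day else numeric(0)

  lab_rows <- which(registry$applies_to == "lab")
  for (grp in split(lab_rows, paste(registry$variable[lab_rows],
                                    registry$window_days[lab_rows]))) {
    v <- registry$variable[grp[1]]
    w <- registry$window_days[grp[1]]
    sel <- which(labs$variable == v & lab_rel >= 0 & lab_rel <= w)
    g <- match(labs$patient_id[sel], ids)
    for (j in grp)
      x[, j] <- aggregate_window(lab_rel[sel], labs$value[sel], g, n,
                                 registry$aggregator[j])
  }

  cult_rows <- which(registry$applies_to == "culture")
  for (grp in split(cult_rows, registry$window_days[cult_rows])) {
    w <- registry$window_days[grp[1]]
    sel <- which(cult_rel >= 0 & cult_rel <= w)
    g <- match(cult$patient_id[sel], ids)
    for (j in grp)
      x[, j] <- aggregate_window(cult_rel[sel], rep(0, length(sel)), g, n,
                                 registry$aggregator[j])
  }

  base_rows <- which(registry$applies_to == "baseline")
  for (j in base_rows) {
    v <- registry$variable[j]
    x[, j] <- as.numeric(cohort$baseline[[v]] == registry$level[j])
  }

  structure(list(x = x, registry = registry, policy = policy,
                 missing_rate = rowMeans(is.na(x))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d patients x %d features (%.1f%% cells missing)\n",
              nrow(x$x), ncol(x$x), 100 * mean(is.na(x$x))))
  invisible(x)
}

#' Per-patient fraction of missing features
#'
#' Missing cells over the registry's feature count, per patient.
#' @param matrix a `feature_matrix`.
#' @return named numeric vector in `[0, 1]`.
#' @export
patient_missing_rate <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (nrow(matrix$x) == 0L) stop_config("feature matrix is empty")
  rowMeans(is.na(matrix$x))
}

#' Write a feature matrix as CSV with a sidecar JSON registry
#'
#' The missing marker serializes as an empty cell.
#' @param matrix a `feature_matrix`.
#' @param csv_path,registry_path output paths.
#' @return invisibly, the paths written.
#' @export
write_feature_matrix <- function(matrix, csv_path,
                                 registry_path = sub("\\.csv$", "_registry.json",
                                                     csv_path)) {
  df <- data.frame(patient_id = rownames(matrix$x), matrix$x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, csv_path, row.names = FALSE, na = "")
  jsonlite::write_json(as.data.frame(matrix$registry), registry_path,
                       digits = NA)
  invisible(c(csv_path, registry_path))
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param csv_path,registry_path input paths.
#' @return a `feature_matrix` (policy not restored).
#' @export
read_feature_matrix <- function(csv_path,
                                registry_path = sub("\\.csv$", "_registry.json",
                                                    csv_path)) {
  df <- utils::read.csv(csv_path, check.names = FALSE, stringsAsFactors = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df$patient_id
  reg <- as.data.frame(jsonlite::read_json(registry_path, simplifyVector = TRUE))
  class(reg) <- c("feature_registry", "data.frame")
  structure(list(x = x, registry = reg, policy = NULL,
                 missing_rate = rowMeans(is.na(x))),
            class = "feature_matrix")
}
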