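# Quarterly drift monitoring: data-shift detection on model inputs and
# confidence, and performance decay on patients whose 2-year outcome has
# matured. Numeric inputs are compared by population-stability index (PSI)
# over reference deciles plus a two-sample Kolmogorov-Smirnov statistic;
# categorical inputs by PSI over categories; flags use a PSI threshold and
# Bonferroni-corrected KS significance.

#' Population stability index
#'
#' For numeric inputs, bins are the reference deciles; for categorical, the
#' union of categories. Empty cells receive a 0.5 pseudo-count before
#' normalization to keep the index finite. PSI is nonnegative and 0 iff the
#' binned distributions are identical.
#'
#' @param reference,current numeric or categorical vectors.
#' @param bins number of quantile bins for numeric inputs (default 10).
#' @return nonnegative scalar.
#' @export
psi <- function(reference, current, bins = 10L) {
  reference <- reference[!is.na(reference)]
  current <- current[!is.na(current)]
  if (!length(reference) || !length(current))
    stop_config("psi needs nonempty reference and current samples")
  if (is.numeric(reference)) {
    brks <- unique(stats::quantile(reference, probs = seq(0, 1, length.out = bins + 1)))
    brks[1] <- -Inf; brks[length(brks)] <- Inf
    if (length(brks) < 2L) brks <- c(-Inf, Inf)
    cr <- table(cut(reference, brks))
    cc <- table(cut(current, brks))
  } else {
    levs <- sort(union(unique(reference), unique(current)))
    cr <- table(factor(reference, levels = levs))
    cc <- table(factor(current, levels = levs))
  }
  cr <- as.numeric(cr); cc <- as.numeric(cc)
  cr[cr == 0] <- 0.5; cc[cc == 0] <- 0.5
  p <- cr / sum(cr); q <- cc / sum(cc)
  sum((p - q) * log(p / q))
}

#' Monitoring configuration
#'
#' @param psi_threshold flag a variable when its PSI exceeds this (default
#'   0.2, the conventional "significant shift" cut).
#' @param ks_alpha KS significance level before multiplicity correction
#'   (default 0.01).
#' @param bonferroni divide `ks_alpha` by the number of monitored variables?
#' @param performance_margin alarm when a matured-performance metric drops
#'   by more than this below the reference (default 0.1).
#' @param bins PSI quantile bins.
#' @return object of class `monitor_config`.
#' @export
monitor_config <- function(psi_threshold = 0.2, ks_alpha = 0.01,
                           bonferroni = TRUE, performance_margin = 0.1,
                           bins = 10L) {
  structure(list(psi_threshold = psi_threshold, ks_alpha = ks_alpha,
                 bonferroni = bonferroni,
                 performance_margin = performance_margin, bins = bins),
            class = "monitor_config")
}

#' Evaluate one monitoring window against the reference
#'
#' `reference` and `current` are lists with components `inputs` (data.frame
#' of numeric and/or categorical variables), and optionally `confidence`
#' (numeric), `risk_factor_counts` (named frequency vectors), and
#' `performance` data: `risk_call` + `label` + logical `matured` columns in
#' an `outcomes` data.frame. A variable is flagged when its PSI exceeds the
#' threshold or (numeric only) its KS test is significant after Bonferroni
#' correction. Performance metrics are computed only on matured patients; an
#' empty matured set is reported as "immature", not an error.
#'
#' @param reference,current window data as described.
#' @param config a [monitor_config()].
#' @return list of class `drift_report`: `variables` (data.frame with psi,
#'   ks_p, flagged), `confidence_shift`, `risk_factor_shift`, `performance`,
#'   `alarm`.
#' @export
evaluate_window <- function(reference, current, config = monitor_config()) {
  if (is.data.frame(reference)) reference <- list(inputs = reference)
  if (is.data.frame(current)) current <- list(inputs = current)
  if (is.null(reference$inputs) || nrow(reference$inputs) == 0L)
    stop_config("reference window is empty")
  if (is.null(current$inputs) || nrow(current$inputs) == 0L)
    stop_config("current window is empty")
  vars <- intersect(names(reference$inputs), names(current$inputs))
  m <- length(vars)
  alpha <- if (isTRUE(config$bonferroni) && m > 0) config$ks_alpha / m
           else config$ks_alpha
  rows <- lapply(vars, function(v) {
    r <- reference$inputs[[v]]; c0 <- current$inputs[[v]]
    s <- psi(r, c0, config$bins)
    ks_p <- if (is.numeric(r) && is.numeric(c0))
      suppressWarnings(stats::ks.test(r[!is.na(r)], c0[!is.na(c0)],
                                      exact = FALSE)$p.value)
    else NA_real_
    data.frame(variable = v, psi = s, ks_p = ks_p,
               flagged = s > config$psi_threshold ||
                 (!is.na(ks_p) && ks_p < alpha),
               stringsAsFactors = FALSE)
  })
  variables <- do.call(rbind, rows)

  confidence_shift <- NULL
  if (!is.null(reference$confidence) && !is.null(current$confidence)) {
    s <- psi(reference$confidence, current$confidence, config$bins)
    confidence_shift <- list(psi = s, flagged = s > config$psi_threshold)
  }
  risk_factor_shift <- NULL
  if (!is.null(reference$risk_factor_counts) &&
      !is.null(current$risk_factor_counts)) {
    feats <- union(names(reference$risk_factor_counts),
                   names(current$risk_factor_counts))
    expand <- function(x) {
      v <- stats::setNames(numeric(length(feats)), feats)
      v[names(x)] <- x
      rep(feats, times = pmax(round(v), 0))
    }
    s <- psi(expand(reference$risk_factor_counts),
             expand(current$risk_factor_counts), config$bins)
    risk_factor_shift <- list(psi = s, flagged = s > config$psi_threshold)
  }

  performance <- list(status = "not_requested")
  perf_drop <- FALSE
  if (!is.null(current$outcomes)) {
    mat <- current$outcomes[isTRUE_vec(current$outcomes$matured), , drop = FALSE]
    if (nrow(mat) == 0L) {
      performance <- list(status = "immature")
    } else {
      met <- classification_metrics(confusion_matrix(mat$risk_call, mat$label))
      performance <- list(status = "matured", n = nrow(mat), metrics = met)
      if (!is.null(reference$outcomes)) {
        rmat <- reference$outcomes[isTRUE_vec(reference$outcomes$matured), ,
                                   drop = FALSE]
        if (nrow(rmat)) {
          rmet <- classification_metrics(
            confusion_matrix(rmat$risk_call, rmat$label))
          performance$reference_metrics <- rmet
          drops <- mapply(function(a, b) !is.na(a) && !is.na(b) &&
                            (b - a) > config$performance_margin,
                          met, rmet)
          perf_drop <- any(drops)
          performance$decayed <- unname(which(drops))
        }
      }
    }
  }
  alarm <- any(variables$flagged) ||
    isTRUE(confidence_shift$flagged) || isTRUE(risk_factor_shift$flagged) ||
    perf_drop
  structure(list(variables = variables, confidence_shift = confidence_shift,
                 risk_factor_shift = risk_factor_shift,
                 performance = performance, alarm = alarm, config = config),
            class = "drift_report")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.drift_report <- function(x, ...) {
  cat(sprintf("Drift report: %d variables monitored, %d flagged — alarm: %s\n",
              nrow(x$variables), sum(x$variables$flagged),
              if (x$alarm) "YES" else "no"))
  fl <- x$variables[x$variables$flagged, , drop = FALSE]
  if (nrow(fl))
    for (i in seq_len(nrow(fl)))
      cat(sprintf("  %s: PSI = %.3f, KS p = %.3g\n", fl$variable[i],
                  fl$psi[i], fl$ks_p[i]))
  if (!is.null(x$confidence_shift))
    cat(sprintf("  confidence PSI = %.3f%s\n", x$confidence_shift$psi,
                if (x$confidence_shift$flagged) " (flagged)" else ""))
  cat(sprintf("  performance: %s\n", x$performance$status))
  invisible(x)
}

#' Export a drift report as JSON with a markdown summary
#' @param report a `drift_report`.
#' @param json_path output JSON path.
#' @param md_path optional markdown summary path.
#' @return invisibly, the paths written.
#' @export
write_drift_report <- function(report, json_path, md_path = NULL) {
  jsonlite::write_json(list(variables = report$variables,
                            confidence_shift = report$confidence_shift,
                            performance = report$performance,
                            alarm = report$alarm),
                       json_path, auto_unbox = TRUE, digits = NA)
  paths <- json_path
  if (!is.null(md_path)) {
    lines <- c("# Drift report",
               sprintf("- alarm: %s", report$alarm),
               sprintf("- flagged variables: %s",
                       paste(report$variables$variable[report$variables$flagged],
                             collapse = ", ")),
               sprintf("- performance: %s", report$performance$status))
    writeLines(lines, md_path)
    paths <- c(paths, md_path)
  }
  invisible(paths)
}

#' Partition a prediction log into monitoring windows
#'
#' Consecutive windows of `window_days` over the span of prediction dates; a
#' trailing remainder shorter than a full window is merged into the last
#' window, which is flagged partial. A patient matures when follow-up covers
#' the 730-day outcome horizon; the maturity day (prediction day + horizon)
#' is assigned to the window containing it.
#'
#' @param log data.frame with `patient_id`, `prediction_day`,
#'   `followup_end_day`.
#' @param window_days window length (default 91).
#' @param horizon_days outcome horizon (default 730).
#' @return list of class `monitoring_windows`; each element has `start`,
#'   `end`, `partial`, `patient_ids` (predicted in window), `matured_ids`
#'   (maturing in window).
#' @export
schedule_windows <- function(log, window_days = 91L, horizon_days = 730L) {
  if (is.null(log) || nrow(log) == 0L)
    return(structure(list(), class = "monitoring_windows"))
  start0 <- min(log$prediction_day)
  span <- max(log$prediction_day) - start0 + 1L
  n_full <- span %/% window_days
  rem <- span %% window_days
  if (n_full == 0L) { n_full <- 1L; rem <- 0L }
  starts <- start0 + (seq_len(n_full) - 1L) * window_days
  ends <- starts + window_days - 1L
  ends[n_full] <- ends[n_full] + rem
  maturity_day <- log$prediction_day + horizon_days
  matures <- log$followup_end_day >= maturity_day
  windows <- lapply(seq_len(n_full), function(i) {
    in_w <- log$prediction_day >= starts[i] & log$prediction_day <= ends[i]
    mat_w <- matures & maturity_day >= starts[i] & maturity_day <= ends[i]
    list(start = starts[i], end = ends[i],
         partial = i == n_full && rem > 0L,
         patient_ids = log$patient_id[in_w],
         matured_ids = log$patient_id[mat_w])
  })
  structure(windows, class = "monitoring_windows")
}

#' @export
print.monitoring_windows <- function(x, ...) {
  cat(sprintf("%d monitoring window(s)\n", length(x)))
  for (w in x)
    cat(sprintf("  [%d, %d]%s: %d predicted, %d matured\n", w$start, w$end,
                if (w$partial) " (partial)" else "",
                length(w$patient_ids), length(w$matured_ids)))
  invisible(x)
}
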