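# Synthetic longitudinal EHR cohorts: baseline characteristics, laboratory
# time series, blood-culture events and a competing-risks composite outcome
# (first of severe infection or CLL treatment after the prediction point).
# The generator exists so that every downstream stage -- featurization,
# ensemble training, benchmarking, harmonization, monitoring -- is testable
# without access to patient-level data.

#' Default synthetic laboratory panel
#'
#' A panel of 33 routine laboratory variables with canonical units, stationary
#' log-normal level parameters, an expected sampling rate per patient-year, and
#' a loading on the patient's latent risk (so that laboratory features carry
#' prognostic signal). Distribution parameters are synthetic by construction;
#' the panel size mirrors the 33 routine laboratory variables a deployed CLL
#' risk model consumes.
#'
#' @param n_labs number of panel variables (<= 33) to keep, in order.
#' @return data.frame with columns `variable`, `unit`, `meanlog`, `sdlog`,
#'   `rate_per_year`, `risk_loading`.
#' @export
default_lab_panel <- function(n_labs = 33L) {
  vars <- c("hemoglobin", "leukocytes", "lymphocytes", "neutrophils",
            "platelets", "crp", "creatinine", "alat", "ldh", "bilirubin",
            "albumin", "sodium", "potassium", "calcium", "urate",
            "alkaline_phosphatase", "ggt", "amylase", "glucose", "hba1c",
            "inr", "aptt", "fibrinogen", "ferritin", "transferrin",
            "haptoglobin", "igg", "iga", "igm", "monocytes", "eosinophils",
            "basophils", "reticulocytes")
  units <- c("mmol/L", "10^9/L", "10^9/L", "10^9/L", "10^9/L", "mg/L",
             "umol/L", "U/L", "U/L", "umol/L", "g/L", "mmol/L", "mmol/L",
             "mmol/L", "mmol/L", "U/L", "U/L", "U/L", "mmol/L", "mmol/mol",
             "ratio", "s", "g/L", "ug/L", "g/L", "g/L", "g/L", "g/L", "g/L",
             "10^9/L", "10^9/L", "10^9/L", "10^9/L")
  n <- length(vars)
  if (n_labs < 1L || n_labs > n) stop_config("'n_labs' must be in 1..%d", n)
  meanlog <- rep(c(2.1, 1.9, 1.2, 1.5, 5.5, 1.6, 4.4, 3.2, 5.2, 2.3, 3.6,
                   4.9, 1.4, 0.9, 5.7, 4.3, 3.4, 3.9, 1.7, 3.7, 0.1, 3.4,
                   1.2, 4.6, 1.0, 0.3, 2.4, 0.7, 0.2, -0.7, -1.6, -2.3, 4.0),
                 length.out = n)
  sdlog <- rep(c(0.15, 0.35, 0.60, 0.30, 0.25, 0.80, 0.25, 0.40, 0.30, 0.35,
                 0.12, 0.02, 0.08, 0.06, 0.25, 0.30, 0.50, 0.40, 0.20, 0.20,
                 0.10, 0.12, 0.25, 0.70, 0.15, 0.45, 0.25, 0.40, 0.50, 0.40,
                 0.60, 0.55, 0.35), length.out = n)
  # A handful of markers track the latent risk; the rest are pure noise.
  loading <- numeric(n)
  loading[c(2, 3, 6, 9, 24, 29)] <- c(0.25, 0.35, 0.30, 0.20, 0.25, -0.20)
  out <- data.frame(variable = vars, unit = units, meanlog = meanlog,
                    sdlog = sdlog, rate_per_year = 4,
                    risk_loading = loading, stringsAsFactors = FALSE)
  out[seq_len(n_labs), , drop = FALSE]
}

# Baseline categorical vocabulary shared by the generator, the feature engine
# and the comparator index. "unknown" is always a representable level.
baseline_variables <- function() {
  list(
    binet    = c("A", "B", "C"),
    ighv     = c("mutated", "unmutated"),
    b2m_high = c("no", "yes"),
    fish     = c("del17p", "del11q", "tri12", "normal", "del13q"),
    ecog     = c("0", "1", "2plus"),
    sex      = c("female", "male"),
    age65    = c("no", "yes")
  )
}

#' Specify a synthetic cohort
#'
#' Assembles and validates the full parameterization of a synthetic cohort:
#' baseline categorical prevalences, the laboratory panel, history depth,
#' blood-culture intensity, the competing-risks outcome model, and a
#' per-variable structured-data missingness profile. The two cause-specific
#' baseline hazards are calibrated analytically (exact expectation over the
#' finite covariate cells, then root finding) so that the expected 2-year
#' composite event rate equals `target_rate_2yr`.
#'
#' @param n_patients cohort size (>= 0).
#' @param seed integer seed; identical `(spec, seed)` reproduce identical
#'   cohorts byte-for-byte.
#' @param baseline_prevalences named list of probability vectors for
#'   `binet`, `ighv`, `b2m_high`, `fish`, `ecog`, `sex` (each summing to 1).
#' @param p_age65 probability that age >= 65 years.
#' @param lab_panel data.frame as [default_lab_panel()].
#' @param history_depth_years length-2 numeric, uniform range of years of
#'   pre-prediction-point laboratory history.
#' @param culture_rate expected blood-culture events per patient-year.
#' @param culture_history_years length-2 numeric range of culture lookback.
#' @param outcome_params list with `beta` (named list of per-level log-hazard
#'   effects), `treatment_fraction` (share of events that are treatment-first),
#'   `censor_range_days` (administrative censoring, uniform, days from the
#'   prediction point) and optionally pre-calibrated `log_base_infection` /
#'   `log_base_treatment` per-day baselines.
#' @param target_rate_2yr expected composite event probability within 730 days
#'   of the prediction point; used to calibrate the baseline hazards unless
#'   both are supplied explicitly.
#' @param missingness_profile named per-variable probability that the
#'   structured value is absent (baseline variables) or that a patient's
#'   laboratory variable is wholly absent.
#' @param prediction_offset_days days from diagnosis to the prediction point.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        seed = 1L,
                        baseline_prevalences = list(
                          binet    = c(A = 0.854, B = 0.119, C = 0.027),
                          ighv     = c(mutated = 0.703, unmutated = 0.297),
                          b2m_high = c(no = 0.88, yes = 0.12),
                          fish     = c(del17p = 0.07, del11q = 0.18,
                                       tri12 = 0.15, normal = 0.25,
                                       del13q = 0.35),
                          ecog     = c(`0` = 0.62, `1` = 0.30, `2plus` = 0.08),
                          sex      = c(female = 0.398, male = 0.602)),
                        p_age65 = 0.701,
                        lab_panel = default_lab_panel(),
                        history_depth_years = c(8, 12),
                        culture_rate = 0.30,
                        culture_history_years = c(8, 12),
                        outcome_params = list(),
                        target_rate_2yr = 0.33,
                        missingness_profile = numeric(),
                        prediction_offset_days = 92L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 0 ||
      n_patients != round(n_patients))
    stop_config("'n_patients' must be a nonnegative integer")
  vocab <- baseline_variables()
  for (v in setdiff(names(vocab), "age65")) {
    p <- baseline_prevalences[[v]]
    if (is.null(p)) stop_config("baseline_prevalences missing variable '%s'", v)
    if (!setequal(names(p), vocab[[v]]))
      stop_config("levels of baseline_prevalences$%s must be {%s}",
                  v, paste(vocab[[v]], collapse = ", "))
    assert_dist(p, paste0("baseline_prevalences$", v))
  }
  assert_prob(p_age65, "p_age65")
  if (nrow(lab_panel) < 1L) stop_config("lab_panel must contain at least one variable")
  if (any(lab_panel$rate_per_year < 0)) stop_config("lab sampling rates must be >= 0")
  if (length(history_depth_years) != 2L || any(history_depth_years < 0))
    stop_config("'history_depth_years' must be a nonnegative range")
  if (culture_rate < 0) stop_config("'culture_rate' must be >= 0")
  assert_prob(target_rate_2yr, "target_rate_2yr")
  if (length(missingness_profile)) {
    assert_prob(unlist(missingness_profile), "missingness_profile")
    known <- c(names(vocab), lab_panel$variable)
    bad <- setdiff(names(missingness_profile), known)
    if (length(bad))
      stop_config("missingness_profile names unknown variable(s): %s (known: %s)",
                  paste(bad, collapse = ", "), paste(known, collapse = ", "))
  }

  op <- outcome_params
  op$beta <- op$beta %||% list(
    binet    = c(A = 0, B = 0.5, C = 0.9),
    ighv     = c(mutated = 0, unmutated = 0.9),
    b2m_high = c(no = 0, yes = 0.6),
    fish     = c(del17p = 0.8, del11q = 0.4, tri12 = 0.1, normal = 0,
                 del13q = -0.1),
    age65    = c(no = 0, yes = 0.4))
  op$treatment_fraction <- op$treatment_fraction %||% 0.45
  assert_prob(op$treatment_fraction, "outcome_params$treatment_fraction")
  op$censor_range_days <- op$censor_range_days %||% c(365, 1825)

  spec <- structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    baseline_prevalences = lapply(baseline_prevalences, function(p) p / sum(p)),
    p_age65 = p_age65, lab_panel = lab_panel,
    history_depth_years = history_depth_years,
    culture_rate = culture_rate,
    culture_history_years = culture_history_years,
    outcome_params = op, target_rate_2yr = target_rate_2yr,
    missingness_profile = missingness_profile,
    prediction_offset_days = as.integer(prediction_offset_days)),
    class = "cohort_spec")

  if (is.null(op$log_base_infection) || is.null(op$log_base_treatment)) {
    base <- calibrate_baseline_hazards(spec)
    spec$outcome_params$log_base_infection <- base[["infection"]]
    spec$outcome_params$log_base_treatment <- base[["treatment"]]
  }
  spec
}

#' Preset cohort specifications
#'
#' `"research"` emulates a development-era registry-backed cohort: complete
#' staging data, ~10-year laboratory histories, 2-year composite event rate
#' 33% and P(age >= 65) = 0.701. `"deployment"` emulates a prospectively
#' deployed hospital EHR: heavy structured-data missingness (Binet 72.2%,
#' IGHV 91.1%, beta-2-microglobulin 35.8%, FISH 99.5%, ECOG 100%), under a
#' year of laboratory history, sparser blood cultures, composite rate 40.6%
#' and P(age >= 65) = 0.764.
#'
#' @param preset `"research"` or `"deployment"`.
#' @param n_patients,seed passed to [cohort_spec()].
#' @param ... further overrides passed to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
cohort_preset <- function(preset = c("research", "deployment"),
                          n_patients = 1000L, seed = 1L, ...) {
  preset <- match.arg(preset)
  args <- list(...)
  if (preset == "research") {
    defaults <- list(
      n_patients = n_patients, seed = seed,
      p_age65 = 0.701, target_rate_2yr = 0.33,
      history_depth_years = c(8, 12), culture_rate = 0.30,
      culture_history_years = c(8, 12),
      outcome_params = list(treatment_fraction = 14.9 / (14.9 + 18.1)),
      missingness_profile = c(binet = 0, ighv = 0.211, b2m_high = 0.236,
                              fish = 0, ecog = 0.004))
  } else {
    defaults <- list(
      n_patients = n_patients, seed = seed,
      baseline_prevalences = list(
        binet    = c(A = 0.881, B = 0.065, C = 0.054),
        ighv     = c(mutated = 0.702, unmutated = 0.298),
        b2m_high = c(no = 0.848, yes = 0.152),
        fish     = c(del17p = 0.07, del11q = 0.18, tri12 = 0.15,
                     normal = 0.25, del13q = 0.35),
        ecog     = c(`0` = 0.62, `1` = 0.30, `2plus` = 0.08),
        sex      = c(female = 0.403, male = 0.597)),
      p_age65 = 0.764, target_rate_2yr = 0.406,
      history_depth_years = c(0.25, 1), culture_rate = 0.15,
      culture_history_years = c(0.25, 1),
      outcome_params = list(treatment_fraction = 17.5 / (17.5 + 23.2)),
      missingness_profile = c(binet = 0.722, ighv = 0.911, b2m_high = 0.358,
                              fish = 0.995, ecog = 1.0))
  }
  defaults[names(args)] <- args
  if (preset == "research" && !("missingness_profile" %in% names(args))) {
    # per-lab dropout: the multi-hospital research registry has roughly
    # twice the per-patient lab-test missingness of the deployment site
    panel <- defaults$lab_panel %||% default_lab_panel()
    defaults$missingness_profile <- c(
      defaults$missingness_profile,
      stats::setNames(rep(0.22, nrow(panel)), panel$variable))
  }
  do.call(cohort_spec, defaults)
}

# Exact expected 2-year composite rate for a given added log-baseline, by
# enumerating the finite covariate cells (all baseline variables entering the
# linear predictor are categorical and independent).
expected_rate_2yr <- function(spec, log_base_total) {
  beta <- spec$outcome_params$beta
  prev <- spec$baseline_prevalences
  prev$age65 <- c(no = 1 - spec$p_age65, yes = spec$p_age65)
  vars <- names(beta)
  grid_p <- 1
  grid_lp <- 0
  for (v in vars) {
    lev <- names(beta[[v]])
    grid_p <- as.vector(outer(grid_p, prev[[v]][lev]))
    grid_lp <- as.vector(outer(grid_lp, beta[[v]][lev], `+`))
  }
  sum(grid_p * (1 - exp(-exp(log_base_total + grid_lp) * 730)))
}

# Calibrate the two cause-specific per-day baseline log-hazards so the
# expected composite 2-year rate matches the target, split between causes by
# treatment_fraction.
calibrate_baseline_hazards <- function(spec) {
  target <- spec$target_rate_2yr
  f <- spec$outcome_params$treatment_fraction
  root <- stats::uniroot(function(c0) expected_rate_2yr(spec, c0) - target,
                         lower = -25, upper = -2, tol = 1e-12)$root
  c(infection = root + log(1 - f), treatment = root + log(f))
}

#' Generate a synthetic cohort
#'
#' Draws `n_patients` longitudinal records under a [cohort_spec()]: baseline
#' categories, laboratory series (stationary log-normal, a subset loading on
#' the latent risk), blood-culture events, and a composite outcome drawn as
#' the first of two cause-specific exponential clocks (infection, treatment)
#' whose log-rates are the calibrated baselines plus the patient's linear
#' predictor. The spec's `missingness_profile` is then applied via
#' [inject_missingness()]. The latent linear predictor is retained in the
#' `latent` component (generator-side ground truth only; never exported to
#' the raw tables).
#'
#' @param spec a `cohort_spec`.
#' @return object of class `ehr_cohort`: a list of data.frames `baseline`
#'   (wide, one row per patient), `labs`, `cultures`, `outcomes`, `latent`,
#'   plus the originating `spec`. All dates are integer day offsets from a
#'   fixed epoch; the prediction point is `diagnosis_day +
#'   prediction_offset_days`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  empty <- function() data.frame(patient_id = character(0))
  if (n == 0L) {
    return(structure(list(
      baseline = data.frame(patient_id = character(0)),
      labs = data.frame(patient_id = character(0), day = integer(0),
                        variable = character(0), value = numeric(0),
                        unit = character(0)),
      cultures = data.frame(patient_id = character(0), day = integer(0)),
      outcomes = data.frame(patient_id = character(0),
                            event_type = character(0), event_day = integer(0),
                            followup_end_day = integer(0)),
      latent = data.frame(patient_id = character(0), latent_risk = numeric(0)),
      spec = spec), class = "ehr_cohort"))
  }
  with_seed(spec$seed, {
    id <- sprintf("P%05d", seq_len(n))
    diagnosis_day <- sample.int(1096L, n, replace = TRUE) - 1L
    pp <- diagnosis_day + spec$prediction_offset_days

    prev <- spec$baseline_prevalences
    draw_cat <- function(p) names(p)[sample.int(length(p), n, replace = TRUE, prob = p)]
    baseline <- data.frame(
      patient_id = id, diagnosis_day = diagnosis_day,
      binet = draw_cat(prev$binet), ighv = draw_cat(prev$ighv),
      b2m_high = draw_cat(prev$b2m_high), fish = draw_cat(prev$fish),
      ecog = draw_cat(prev$ecog), sex = draw_cat(prev$sex),
      stringsAsFactors = FALSE)
    # age: normal with sd 11y, mean set so P(age >= 65) hits the preset.
    age_mean <- 65 - stats::qnorm(1 - spec$p_age65) * 11
    baseline$age <- round(pmax(30, stats::rnorm(n, age_mean, 11)), 1)
    baseline$age65 <- ifelse(baseline$age >= 65, "yes", "no")

    beta <- spec$outcome_params$beta
    lp <- numeric(n)
    for (v in names(beta)) lp <- lp + unname(beta[[v]][baseline[[v]]])

    # competing exponential clocks, per-day rates
    op <- spec$outcome_params
    rate_inf <- exp(op$log_base_infection + lp)
    rate_trt <- exp(op$log_base_treatment + lp)
    total <- rate_inf + rate_trt
    t_event <- stats::rexp(n, rate = total)
    cause <- ifelse(stats::runif(n) < rate_trt / total, "treatment", "infection")
    censor <- stats::runif(n, op$censor_range_days[1], op$censor_range_days[2])
    followup_end <- pp + as.integer(ceiling(censor))
    event_day <- pp + as.integer(ceiling(t_event))
    has_event <- event_day <= followup_end
    outcomes <- data.frame(
      patient_id = id,
      event_type = ifelse(has_event, cause, "none"),
      event_day = ifelse(has_event, event_day, NA_integer_),
      followup_end_day = followup_end, stringsAsFactors = FALSE)

    depth_days <- stats::runif(n, spec$history_depth_years[1],
                               spec$history_depth_years[2]) * 365.25
    hist_start <- pp - as.integer(ceiling(depth_days))

    panel <- spec$lab_panel
    span_years <- (followup_end - hist_start) / 365.25
    labs_list <- vector("list", nrow(panel))
    for (j in seq_len(nrow(panel))) {
      k <- stats::rpois(n, panel$rate_per_year[j] * span_years)
      pid <- rep.int(seq_len(n), k)
      m <- length(pid)
      if (m == 0L) next
      day <- hist_start[pid] +
        as.integer(floor(stats::runif(m) * (followup_end[pid] - hist_start[pid] + 1L)))
      # canonical lab values carry 12 significant digits (finite measurement
      # precision; makes correct-dictionary unit round-trips exact)
      value <- signif(stats::rlnorm(m, panel$meanlog[j] +
                                      panel$risk_loading[j] * lp[pid],
                                    panel$sdlog[j]), 12)
      labs_list[[j]] <- data.frame(
        patient_id = id[pid], day = day, variable = panel$variable[j],
        value = value, unit = panel$unit[j], stringsAsFactors = FALSE)
    }
    labs <- do.call(rbind, labs_list[!vapply(labs_list, is.null, logical(1))])
    if (is.null(labs))
      labs <- data.frame(patient_id = character(0), day = integer(0),
                         variable = character(0), value = numeric(0),
                         unit = character(0))
    labs <- labs[order(labs$patient_id, labs$variable, labs$day), , drop = FALSE]
    rownames(labs) <- NULL

    cult_span <- pmin(stats::runif(n, spec$culture_history_years[1],
                                   spec$culture_history_years[2]) * 365.25,
                      pp - hist_start) + (followup_end - pp)
    kc <- stats::rpois(n, spec$culture_rate * cult_span / 365.25)
    pidc <- rep.int(seq_len(n), kc)
    cultures <- if (length(pidc)) {
      start <- followup_end[pidc] - as.integer(ceiling(cult_span[pidc]))
      data.frame(patient_id = id[pidc],
                 day = start + as.integer(floor(stats::runif(length(pidc)) *
                        (followup_end[pidc] - start + 1L))),
                 stringsAsFactors = FALSE)
    } else data.frame(patient_id = character(0), day = integer(0))
    cultures <- cultures[order(cultures$patient_id, cultures$day), , drop = FALSE]
    rownames(cultures) <- NULL

    cohort <- structure(list(
      baseline = baseline, labs = labs, cultures = cultures,
      outcomes = outcomes,
      latent = data.frame(patient_id = id, latent_risk = lp,
                          stringsAsFactors = FALSE),
      spec = spec), class = "ehr_cohort")
    if (length(spec$missingness_profile))
      cohort <- inject_missingness(cohort, spec$missingness_profile)
    cohort
  })
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat(sprintf("Synthetic EHR cohort: %d patients, %d lab events, %d culture events\n",
              nrow(x$baseline), nrow(x$labs), nrow(x$cultures)))
  if (nrow(x$outcomes)) {
    tab <- table(x$outcomes$event_type)
    cat("First events:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Prediction points of a cohort
#' @param cohort an `ehr_cohort`.
#' @param offset_days days from diagnosis; defaults to the cohort spec's value.
#' @return named integer vector of prediction-point days per patient.
#' @export
prediction_points <- function(cohort, offset_days = NULL) {
  offset_days <- offset_days %||% cohort$spec$prediction_offset_days %||% 92L
  stats::setNames(cohort$baseline$diagnosis_day + offset_days,
                  cohort$baseline$patient_id)
}

#' Inject structured-data missingness into a cohort
#'
#' Baseline variables are independently replaced by `"unknown"` with their
#' configured probability; laboratory variables are dropped wholesale per
#' patient with theirs. The input cohort is not modified.
#'
#' @param cohort an `ehr_cohort`.
#' @param profile named numeric vector of per-variable missingness
#'   probabilities (baseline variable names and/or lab panel variable names).
#' @return a new `ehr_cohort`.
#' @export
inject_missingness <- function(cohort, profile) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  profile <- unlist(profile)
  assert_prob(profile, "profile")
  base_vars <- names(baseline_variables())
  lab_vars <- unique(c(cohort$spec$lab_panel$variable, cohort$labs$variable))
  known <- c(base_vars, lab_vars)
  bad <- setdiff(names(profile), known)
  if (length(bad))
    stop_config("unknown variable(s) in missingness profile: %s (known: %s)",
                paste(bad, collapse = ", "), paste(known, collapse = ", "))
  n <- nrow(cohort$baseline)
  out <- cohort
  for (v in intersect(names(profile), base_vars)) {
    p <- profile[[v]]
    if (p > 0) {
      hit <- stats::runif(n) < p
      out$baseline[[v]][hit] <- "unknown"
      if (v == "age65") out$baseline$age[hit] <- NA_real_
    }
  }
  drop_lab <- intersect(names(profile), lab_vars)
  if (length(drop_lab) && nrow(out$labs)) {
    keep <- rep(TRUE, nrow(out$labs))
    for (v in drop_lab) {
      p <- profile[[v]]
      if (p > 0) {
        hit_pat <- cohort$baseline$patient_id[stats::runif(n) < p]
        keep[out$labs$variable == v & out$labs$patient_id %in% hit_pat] <- FALSE
      }
    }
    out$labs <- out$labs[keep, , drop = FALSE]
    rownames(out$labs) <- NULL
  }
  out
}

#' Describe a source dialect
#'
#' A source dialect renames canonical variables and re-expresses laboratory
#' values in source units, emulating an EHR extract before harmonization.
#' Unit conversions are linear: `canonical = factor * source + offset`.
#' An optional `corruption` perturbs the rendered values of named variables
#' (the dictionary is left untouched), so harmonizing with the otherwise
#' correct dictionary fails exactly on those variables.
#'
#' @param name_scramble named character vector, canonical variable ->
#'   source label (must be one-to-one).
#' @param unit_scramble data.frame with columns `variable`, `canonical_unit`,
#'   `source_unit`, `factor`, `offset`.
#' @param corruption optional named numeric vector: variable ->
#'   multiplicative error applied to the rendered source values.
#' @return object of class `source_dialect`.
#' @export
source_dialect <- function(name_scramble, unit_scramble,
                           corruption = NULL) {
  if (anyDuplicated(name_scramble) || anyDuplicated(names(name_scramble)))
    stop_config("name_scramble must be invertible (one-to-one)")
  if (any(unit_scramble$factor == 0)) stop_config("unit factors must be nonzero")
  structure(list(name_scramble = name_scramble,
                 unit_scramble = unit_scramble,
                 corruption = corruption),
            class = "source_dialect")
}

#' Identity dialect for a cohort
#' @param cohort an `ehr_cohort`.
#' @return a `source_dialect` that renames nothing and converts nothing.
#' @export
identity_dialect <- function(cohort) {
  panel <- cohort$spec$lab_panel
  vars <- c(names(baseline_variables()), panel$variable)
  source_dialect(
    name_scramble = stats::setNames(vars, vars),
    unit_scramble = data.frame(variable = panel$variable,
                               canonical_unit = panel$unit,
                               source_unit = panel$unit,
                               factor = 1, offset = 0,
                               stringsAsFactors = FALSE))
}

#' Random non-trivial dialect for a cohort
#'
#' Scrambles every variable name (upper-case site-style labels) and assigns a
#' random linear unit conversion per laboratory variable.
#' @param cohort an `ehr_cohort`.
#' @param seed integer seed.
#' @param corruption optional, as in [source_dialect()].
#' @return a `source_dialect`.
#' @export
random_dialect <- function(cohort, seed = 1L, corruption = NULL) {
  panel <- cohort$spec$lab_panel
  vars <- c(names(baseline_variables()), panel$variable)
  with_seed(seed, {
    labels <- paste0("SRC_", toupper(vars), "_",
                     sample(100:999, length(vars)))
    factor <- round(stats::runif(nrow(panel), 0.1, 20), 4)
    offset <- round(stats::runif(nrow(panel), -5, 5), 4)
    source_dialect(
      name_scramble = stats::setNames(labels, vars),
      unit_scramble = data.frame(variable = panel$variable,
                                 canonical_unit = panel$unit,
                                 source_unit = paste0("u[", panel$variable, "]"),
                                 factor = factor, offset = offset,
                                 stringsAsFactors = FALSE),
      corruption = corruption)
  })
}

#' Canonical long-format export tables of a cohort
#'
#' The canonical serialization: `baseline` long (patient_id, diagnosis_day,
#' variable, category), `labs`, `cultures` and `outcomes`. Numeric age is
#' carried as variable `age_years` with a full-precision character category
#' so the export round-trips exactly. The latent risk is never exported here.
#'
#' @param cohort an `ehr_cohort`.
#' @return object of class `raw_tables` (list of four data.frames).
#' @export
export_tables <- function(cohort) {
  b <- cohort$baseline
  vars <- names(baseline_variables())
  long <- do.call(rbind, lapply(vars, function(v)
    data.frame(patient_id = b$patient_id, diagnosis_day = b$diagnosis_day,
               variable = v, category = b[[v]], stringsAsFactors = FALSE)))
  long <- rbind(long, data.frame(
    patient_id = b$patient_id, diagnosis_day = b$diagnosis_day,
    variable = "age_years",
    category = vapply(b$age, function(a)
      if (is.na(a)) "unknown" else format(a, digits = 17), character(1)),
    stringsAsFactors = FALSE))
  structure(list(baseline = long, labs = cohort$labs,
                 cultures = cohort$cultures, outcomes = cohort$outcomes),
            class = "raw_tables")
}

#' Render a cohort through a source dialect
#'
#' Emits raw source tables with scrambled variable labels and laboratory
#' values expressed in source units (`source = (canonical - offset) /
#' factor`), so that harmonization with the matching dictionaries exactly
#' recovers the canonical values.
#'
#' @param cohort an `ehr_cohort`.
#' @param dialect a `source_dialect` covering every variable present.
#' @return a `raw_tables` object in the source dialect.
#' @export
render_source <- function(cohort, dialect) {
  stopifnot(inherits(cohort, "ehr_cohort"), inherits(dialect, "source_dialect"))
  tabs <- export_tables(cohort)
  ns <- dialect$name_scramble
  present <- unique(c(tabs$baseline$variable[tabs$baseline$variable != "age_years"],
                      tabs$labs$variable))
  uncovered <- setdiff(present, names(ns))
  if (length(uncovered))
    stop_config("dialect does not cover variable(s): %s",
                paste(uncovered, collapse = ", "))
  keep_age <- tabs$baseline$variable == "age_years"
  tabs$baseline$variable[!keep_age] <- unname(ns[tabs$baseline$variable[!keep_age]])
  if (nrow(tabs$labs)) {
    um <- dialect$unit_scramble
    i <- match(tabs$labs$variable, um$variable)
    if (anyNA(i))
      stop_config("dialect unit map does not cover variable(s): %s",
                  paste(unique(tabs$labs$variable[is.na(i)]), collapse = ", "))
    fac <- um$factor[i]
    if (!is.null(dialect$corruption)) {
      corr <- dialect$corruption[tabs$labs$variable]
      fac <- fac * ifelse(is.na(corr), 1, corr)
    }
    tabs$labs$value <- (tabs$labs$value - um$offset[i]) / fac
    tabs$labs$unit <- um$source_unit[i]
    tabs$labs$variable <- unname(ns[tabs$labs$variable])
  }
  tabs
}

#' Correct harmonization dictionaries for a dialect
#'
#' The inverse of [render_source()]: a name dictionary (source label ->
#' canonical variable) and a unit dictionary (canonical variable, source unit,
#' factor, offset) that recover canonical values exactly.
#' @param dialect a `source_dialect`.
#' @return list with elements `name_map` and `unit_map`.
#' @export
dialect_maps <- function(dialect) {
  list(name_map = stats::setNames(names(dialect$name_scramble),
                                  unname(dialect$name_scramble)),
       unit_map = dialect$unit_scramble)
}

#' Write cohort export tables (and the generator truth file) to disk
#'
#' @param cohort an `ehr_cohort`.
#' @param dir output directory (created if needed).
#' @param truth write `truth.json` with per-patient latent risk?
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, truth = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- export_tables(cohort)
  paths <- character(0)
  for (nm in c("baseline", "labs", "cultures", "outcomes")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tabs[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (truth) {
    p <- file.path(dir, "truth.json")
    jsonlite::write_json(cohort$latent, p, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read raw source tables from a directory of CSV exports
#' @param dir directory containing `baseline.csv`, `labs.csv`, `cultures.csv`,
#'   `outcomes.csv`.
#' @return a `raw_tables` object.
#' @export
read_raw_tables <- function(dir) {
  rd <- function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(p)) stop_config("missing input file: %s", p)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  structure(list(baseline = rd("baseline"), labs = rd("labs"),
                 cultures = rd("cultures"), outcomes = rd("outcomes")),
            class = "raw_tables")
}
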