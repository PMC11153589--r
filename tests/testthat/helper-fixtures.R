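# Fixtures are built in code at test time; nothing is stored on disk.

# A reduced laboratory panel keeps featurization and training fast while
# preserving risk-loaded variables (lymphocytes, crp at indices 3 and 6).
small_panel <- function(n = 6L) default_lab_panel(n)

# Small preset cohort for integration-style tests.
small_cohort <- function(n = 80L, seed = 1L, preset = "research", ...) {
  generate_cohort(cohort_preset(preset, n_patients = n, seed = seed,
                                lab_panel = small_panel(), ...))
}

# Hand-built cohort with fully controlled events, for by-hand oracles.
# baseline defaults: one fully observed Binet-A patient profile per id.
manual_cohort <- function(ids, diagnosis_day = 0L,
                          labs = NULL, cultures = NULL, outcomes = NULL,
                          baseline_overrides = list(),
                          lab_panel = small_panel(2L)) {
  n <- length(ids)
  baseline <- data.frame(
    patient_id = ids, diagnosis_day = rep_len(diagnosis_day, n),
    binet = "A", ighv = "mutated", b2m_high = "no", fish = "normal",
    ecog = "0", sex = "female", age = 60, age65 = "no",
    stringsAsFactors = FALSE)
  for (nm in names(baseline_overrides))
    baseline[[nm]] <- rep_len(baseline_overrides[[nm]], n)
  if (is.null(labs))
    labs <- data.frame(patient_id = character(0), day = integer(0),
                       variable = character(0), value = numeric(0),
                       unit = character(0))
  if (is.null(cultures))
    cultures <- data.frame(patient_id = character(0), day = integer(0))
  if (is.null(outcomes))
    outcomes <- data.frame(patient_id = ids, event_type = "none",
                           event_day = NA_integer_,
                           followup_end_day = rep_len(diagnosis_day, n) + 2000L,
                           stringsAsFactors = FALSE)
  structure(list(baseline = baseline, labs = labs, cultures = cultures,
                 outcomes = outcomes,
                 latent = data.frame(patient_id = ids, latent_risk = 0),
                 spec = list(lab_panel = lab_panel,
                             prediction_offset_days = 92L)),
            class = "ehr_cohort")
}

# Reduced ensemble (one learner per family + an extra boosted tree) so
# family-specific behaviour is exercised cheaply; 6 learners, 4/1/1 targets.
small_config <- function(seed = 1L, ...) {
  ensemble_config(n_boosted = 2L, n_random_forest = 1L, n_extra_trees = 1L,
                  n_elastic_net = 1L, n_logistic = 1L,
                  outcome_split = c(composite = 4L, treatment = 1L,
                                    infection = 1L),
                  seed = seed,
                  hyperparameters = list(
                    boosted_trees_native_missing = list(nrounds = 25L),
                    random_forest = list(num.trees = 80L),
                    extremely_randomized_trees = list(num.trees = 80L)),
                  ...)
}

# Train a small model on a small cohort; memoised per test file run.
fit_small_model <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 120L, seed = 1L) {
    key <- paste0("m", n, "_", seed)
    if (!is.null(cache[[key]])) return(cache[[key]])
    co <- small_cohort(n = n, seed = seed)
    reg <- default_registry(co$spec$lab_panel)
    fm <- extract_features(co, reg)
    model <- train_ensemble(fm, training_labels(co), small_config(seed = seed))
    cache[[key]] <- list(cohort = co, registry = reg, features = fm,
                         model = model)
    cache[[key]]
  }
})
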