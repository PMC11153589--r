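# Run configuration, logging, and the command-line surface binding the
# pipeline stages (simulate -> harmonize -> featurize -> train -> predict ->
# evaluate -> monitor) into reproducible runs. Every artifact directory
# receives a run log embedding the config hash and seed that produced it.

#' Hash a configuration object
#'
#' MD5 of the canonical JSON serialization; used to stamp artifacts so a run
#' is reproducible from its archived configuration.
#' @param config any JSON-serializable list.
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_run_log <- function(out_dir, subcommand, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(subcommand = subcommand, config = config,
              config_hash = config_hash(config),
              package_version = as.character(utils::packageVersion("ehrisk")),
              r_version = R.version.string)
  jsonlite::write_json(log, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("[ehrisk %s] config hash %s", subcommand, log$config_hash))
  invisible(log)
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop_config("unexpected argument '%s'", a)
    key <- substring(a, 3)
    if (i + 1L <= length(args) && !startsWith(args[i + 1L], "--")) {
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      flags[[key]] <- TRUE
      i <- i + 1L
    }
  }
  flags
}

need_file <- function(path) {
  if (is.null(path) || !file.exists(path))
    stop(errorCondition(sprintf("missing input file: %s", path %||% "(unset)"),
                        class = c("ehrisk_io_error", "error")))
  path
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions, used by the `inst/cli/ehrisk`
#' script. Subcommands: `simulate`, `featurize`, `train`, `predict`,
#' `evaluate`, `harmonize`, `monitor`. Returns (invisibly) exit status 0 on
#' success, 2 on a missing input file, 3 on an invalid configuration.
#'
#' @param args character vector of command-line arguments
#'   (`commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status, invisibly.
#' @export
ehrisk_main <- function(args) {
  status <- tryCatch({
    if (length(args) < 1L) stop_config("usage: ehrisk <subcommand> [--flags]")
    sub <- args[1]
    flags <- parse_flags(args[-1])
    seed <- as.integer(flags$seed %||% 1L)
    out <- flags$out %||% "."
    switch(sub,
      simulate = {
        spec <- cohort_preset(flags$preset %||% "research",
                              n_patients = as.integer(flags$n %||% 500L),
                              seed = seed)
        cohort <- generate_cohort(spec)
        write_cohort(cohort, out)
        write_run_log(out, "simulate", list(preset = flags$preset %||% "research",
                                            n = spec$n_patients, seed = seed))
      },
      featurize = {
        raw <- read_raw_tables(need_file(flags$`in`))
        panel <- default_lab_panel()
        ident <- stats::setNames(c(names(baseline_variables()), panel$variable),
                                 c(names(baseline_variables()), panel$variable))
        umap <- data.frame(variable = panel$variable,
                           canonical_unit = panel$unit,
                           source_unit = panel$unit, factor = 1, offset = 0)
        cohort <- harmonize(raw, ident, umap, lab_panel = panel)
        fm <- extract_features(cohort, default_registry(panel))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_feature_matrix(fm, file.path(out, "features.csv"))
        write_run_log(out, "featurize", list(input = flags$`in`, seed = seed))
      },
      train = {
        fm <- read_feature_matrix(need_file(flags$features))
        raw <- read_raw_tables(need_file(flags$cohort))
        panel <- default_lab_panel()
        ident <- stats::setNames(c(names(baseline_variables()), panel$variable),
                                 c(names(baseline_variables()), panel$variable))
        umap <- data.frame(variable = panel$variable,
                           canonical_unit = panel$unit,
                           source_unit = panel$unit, factor = 1, offset = 0)
        cohort <- harmonize(raw, ident, umap, lab_panel = panel)
        labels <- training_labels(cohort)
        model <- train_ensemble(fm, labels, ensemble_config(seed = seed))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        save_ensemble(model, file.path(out, "model.rds"))
        write_run_log(out, "train", list(features = flags$features, seed = seed))
      },
      predict = {
        model <- load_ensemble(need_file(flags$model))
        fm <- read_feature_matrix(need_file(flags$features))
        pred <- predict(model, fm)
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_predictions(pred, file.path(out, "predictions.csv"))
        write_run_log(out, "predict", list(model = flags$model,
                                           features = flags$features))
      },
      evaluate = {
        pred <- utils::read.csv(need_file(flags$predictions),
                                stringsAsFactors = FALSE)
        raw <- read_raw_tables(need_file(flags$cohort))
        cohort <- structure(list(baseline = data.frame(
          patient_id = unique(raw$outcomes$patient_id)),
          outcomes = raw$outcomes), class = "ehr_cohort")
        # reconstruct diagnosis days from the baseline export
        dd <- raw$baseline[!duplicated(raw$baseline$patient_id), ]
        cohort$baseline$diagnosis_day <-
          dd$diagnosis_day[match(cohort$baseline$patient_id, dd$patient_id)]
        labels <- label_outcomes(cohort)
        rep <- confidence_strata_benchmark(
          pred, labels, config = bootstrap_config(
            replicates = as.integer(flags$replicates %||% 1000L), seed = seed))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_benchmark_report(rep, file.path(out, "benchmark.json"))
        write_run_log(out, "evaluate", list(predictions = flags$predictions,
                                            seed = seed))
      },
      harmonize = {
        raw <- read_raw_tables(need_file(flags$`in`))
        maps <- read_dictionaries(need_file(flags$`name-map`),
                                  need_file(flags$`unit-map`))
        cohort <- harmonize(raw, maps$name_map, maps$unit_map)
        write_cohort(cohort, out, truth = FALSE)
        unmapped <- attr(cohort, "unmapped")
        jsonlite::write_json(unmapped, file.path(out, "unmapped.json"),
                             auto_unbox = TRUE)
        write_run_log(out, "harmonize", list(input = flags$`in`))
      },
      monitor = {
        ref <- utils::read.csv(need_file(flags$reference),
                               stringsAsFactors = FALSE)
        cur <- utils::read.csv(need_file(flags$current),
                               stringsAsFactors = FALSE)
        report <- evaluate_window(list(inputs = ref), list(inputs = cur))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_drift_report(report, file.path(out, "drift.json"),
                           file.path(out, "drift.md"))
        write_run_log(out, "monitor", list(reference = flags$reference,
                                           current = flags$current))
      },
      stop_config("unknown subcommand '%s' (expected simulate, featurize, train, predict, evaluate, harmonize, monitor)",
                  sub))
    0L
  },
  ehrisk_io_error = function(e) { message("error: ", conditionMessage(e)); 2L },
  ehrisk_config_error = function(e) { message("error: ", conditionMessage(e)); 3L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
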