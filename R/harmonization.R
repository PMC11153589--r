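# Dictionary-based harmonization of raw source tables into the model's
# canonical vocabulary, validated by per-patient prediction matching across
# sources: a mapping is accepted only when, for the same patients, the model
# produces the identical risk call, confidence, and personalized risk
# factors from either source. Residual mismatches are localized from feature
# contributions back to the offending variables.

#' Harmonize raw source tables into a canonical cohort
#'
#' Applies the two many-to-one dictionaries: `name_map` (source label ->
#' canonical variable) and `unit_map` (canonical variable + source unit ->
#' linear transform `canonical = factor * source + offset`, plus the
#' canonical unit label). Rows whose label or unit is not covered are routed
#' to an unmapped-rows report attached as attribute `"unmapped"` — never
#' silently dropped.
#'
#' @param raw a `raw_tables` object ([render_source()], [read_raw_tables()]).
#' @param name_map named character vector: source label -> canonical
#'   variable.
#' @param unit_map data.frame with columns `variable`, `canonical_unit`,
#'   `source_unit`, `factor`, `offset`.
#' @param lab_panel optional canonical panel used to carry generator
#'   metadata into the reconstructed cohort spec.
#' @return an `ehr_cohort` (without latent truth), with attribute
#'   `"unmapped"` (list of unmapped baseline / lab row counts by label).
#' @export
harmonize <- function(raw, name_map, unit_map, lab_panel = NULL) {
  stopifnot(inherits(raw, "raw_tables"))
  if (any(unit_map$factor == 0)) stop_config("unit_map factors must be nonzero")
  unmapped <- list(baseline = character(0), labs = character(0))

  base_long <- raw$baseline
  is_age <- base_long$variable == "age_years"
  canon <- unname(name_map[base_long$variable])
  canon[is_age] <- "age_years"
  bad <- !is_age & is.na(canon)
  unmapped$baseline <- unique(base_long$variable[bad])
  base_long <- base_long[!bad, , drop = FALSE]
  base_long$variable <- canon[!bad]

  ids <- unique(raw$outcomes$patient_id)
  baseline <- data.frame(
    patient_id = ids,
    diagnosis_day = base_long$diagnosis_day[match(ids, base_long$patient_id)],
    stringsAsFactors = FALSE)
  for (v in names(baseline_variables())) {
    rows <- base_long[base_long$variable == v, ]
    val <- rows$category[match(ids, rows$patient_id)]
    baseline[[v]] <- ifelse(is.na(val), "unknown", val)
  }
  age_rows <- base_long[base_long$variable == "age_years", ]
  age_chr <- age_rows$category[match(ids, age_rows$patient_id)]
  baseline$age <- suppressWarnings(as.numeric(age_chr))

  labs <- raw$labs
  if (nrow(labs)) {
    lab_canon <- unname(name_map[labs$variable])
    bad_name <- is.na(lab_canon)
    key <- paste(lab_canon, labs$unit, sep = "\r")
    ukey <- paste(unit_map$variable, unit_map$source_unit, sep = "\r")
    i <- match(key, ukey)
    bad_unit <- !bad_name & is.na(i)
    bad <- bad_name | bad_unit
    unmapped$labs <- unique(labs$variable[bad])
    keep <- which(!bad)
    labs <- data.frame(patient_id = labs$patient_id[keep],
                       day = labs$day[keep],
                       variable = lab_canon[keep],
                       # canonical values are 12-significant-digit; rounding
                       # here makes a correct linear conversion bit-exact
                       value = signif(unit_map$factor[i[keep]] * labs$value[keep] +
                                        unit_map$offset[i[keep]], 12),
                       unit = unit_map$canonical_unit[i[keep]],
                       stringsAsFactors = FALSE)
  }

  panel <- lab_panel %||% unique(data.frame(variable = unit_map$variable,
                                            unit = unit_map$canonical_unit,
                                            stringsAsFactors = FALSE))
  spec <- list(lab_panel = panel, prediction_offset_days = 92L)
  cohort <- structure(list(baseline = baseline, labs = labs,
                           cultures = raw$cultures, outcomes = raw$outcomes,
                           latent = NULL, spec = spec),
                      class = "ehr_cohort")
  attr(cohort, "unmapped") <- unmapped
  cohort
}

#' Read harmonization dictionaries from CSV
#'
#' `name_path`: two columns `source_label,canonical`; `unit_path`: columns
#' `variable,canonical_unit,source_unit,factor,offset`.
#' @param name_path,unit_path CSV paths.
#' @return list with `name_map` (named character) and `unit_map` (data.frame).
#' @export
read_dictionaries <- function(name_path, unit_path) {
  nm <- utils::read.csv(name_path, stringsAsFactors = FALSE)
  um <- utils::read.csv(unit_path, stringsAsFactors = FALSE)
  list(name_map = stats::setNames(nm$canonical, nm$source_label),
       unit_map = um)
}

#' Write harmonization dictionaries to CSV
#' @param maps list with `name_map`, `unit_map` ([dialect_maps()]).
#' @param name_path,unit_path output CSV paths.
#' @return invisibly, the paths.
#' @export
write_dictionaries <- function(maps, name_path, unit_path) {
  utils::write.csv(data.frame(source_label = names(maps$name_map),
                              canonical = unname(maps$name_map)),
                   name_path, row.names = FALSE)
  utils::write.csv(maps$unit_map, unit_path, row.names = FALSE)
  invisible(c(name_path, unit_path))
}

predict_with_factors <- function(model, cohort, registry, policy, thresholds,
                                 top = 5L) {
  fm <- extract_features(cohort, registry, policy)
  pred <- predict(model, fm, thresholds)
  contrib <- attribute_risk_factors(model, fm)
  list(pred = pred, contrib = contrib)
}

top_factor_ids <- function(v, top = 5L) {
  ord <- order(-abs(v), names(v))
  v <- v[ord]
  list(up = names(v[v > 0])[seq_len(min(top, sum(v > 0)))],
       down = names(v[v < 0])[seq_len(min(top, sum(v < 0)))])
}

#' Match predictions for the same patients across two data sources
#'
#' A patient matches iff the risk calls agree, the absolute confidence
#' difference is within `tol`, and the top-5 up and top-5 down risk-factor
#' lists are identical in membership and order. The default `tol = 0`
#' demands a bit-identical confidence — the termination condition of the
#' harmonization loop.
#'
#' @param model a fitted `cll_ensemble`.
#' @param cohort_a,cohort_b two `ehr_cohort`s carrying the same patient ids.
#' @param registry,policy featurization settings.
#' @param thresholds a [confidence_thresholds()].
#' @param tol confidence tolerance (default 0).
#' @return list of class `match_report`: per-patient data.frame (`risk_match`,
#'   `delta_confidence`, `factors_match`, `matched`), `matched_fraction`,
#'   `implicated_features`, `implicated_variables`, plus the raw contribution
#'   matrices.
#' @export
match_predictions <- function(model, cohort_a, cohort_b,
                              registry = NULL,
                              policy = prediction_point_policy(),
                              thresholds = confidence_thresholds(),
                              tol = 0) {
  registry <- registry %||% model$registry
  ids_a <- cohort_a$baseline$patient_id
  ids_b <- cohort_b$baseline$patient_id
  if (!setequal(ids_a, ids_b))
    stop_config("patient ids differ between sources: %s",
                paste(union(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a)),
                      collapse = ", "))
  pa <- predict_with_factors(model, cohort_a, registry, policy, thresholds)
  pb <- predict_with_factors(model, cohort_b, registry, policy, thresholds)
  ord <- match(ids_a, pb$pred$patient_id)
  pb$pred <- pb$pred[ord, ]
  pb$contrib <- pb$contrib[ids_a, , drop = FALSE]
  pa$contrib <- pa$contrib[ids_a, , drop = FALSE]

  risk_match <- pa$pred$risk_call == pb$pred$risk_call
  dconf <- abs(pa$pred$confidence - pb$pred$confidence)
  factors_match <- vapply(seq_along(ids_a), function(i) {
    fa <- top_factor_ids(pa$contrib[i, ])
    fb <- top_factor_ids(pb$contrib[i, ])
    identical(fa, fb)
  }, logical(1))
  matched <- risk_match & dconf <= tol & factors_match
  per_patient <- data.frame(patient_id = ids_a, risk_match = risk_match,
                            delta_confidence = dconf,
                            factors_match = factors_match, matched = matched,
                            stringsAsFactors = FALSE)
  diff_feat <- abs(pa$contrib - pb$contrib) > tol
  implicated_features <- sort(colSums(diff_feat[!matched, , drop = FALSE]),
                              decreasing = TRUE)
  implicated_features <- implicated_features[implicated_features > 0]
  vars <- registry$variable[match(names(implicated_features),
                                  registry$feature_id)]
  implicated_variables <- sort(tapply(implicated_features, vars, sum),
                               decreasing = TRUE)
  structure(list(per_patient = per_patient,
                 matched_fraction = mean(matched),
                 implicated_features = implicated_features,
                 implicated_variables = implicated_variables,
                 contrib_a = pa$contrib, contrib_b = pb$contrib, tol = tol),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("Prediction match across sources: %.1f%% of %d patients matched\n",
              100 * x$matched_fraction, nrow(x$per_patient)))
  if (length(x$implicated_variables))
    cat("Implicated variables:",
        paste(sprintf("%s (%d)", names(x$implicated_variables),
                      as.integer(x$implicated_variables)), collapse = ", "),
        "\n")
  invisible(x)
}

#' Localize prediction mismatches to variables
#'
#' Among mismatched patients, features whose per-patient contributions
#' differ by more than `tol` across sources are implicated and mapped back
#' to their variables via the registry, ranked by the number of affected
#' patients.
#'
#' @param report a `match_report`.
#' @param registry the feature registry used for matching.
#' @return data.frame with `variable`, `n_patients` (affected), sorted
#'   decreasing.
#' @export
localize_discrepancies <- function(report, registry) {
  bad <- !report$per_patient$matched
  if (!any(bad))
    return(data.frame(variable = character(0), n_patients = integer(0)))
  diff_feat <- abs(report$contrib_a - report$contrib_b) > report$tol
  diff_feat <- diff_feat[bad, , drop = FALSE]
  per_feat <- colSums(diff_feat)
  per_feat <- per_feat[per_feat > 0]
  if (!length(per_feat))
    return(data.frame(variable = character(0), n_patients = integer(0)))
  vars <- registry$variable[match(names(per_feat), registry$feature_id)]
  # count patients affected through any feature of the variable
  counts <- vapply(unique(vars), function(v) {
    cols <- names(per_feat)[vars == v]
    sum(rowSums(diff_feat[, cols, drop = FALSE]) > 0)
  }, numeric(1))
  out <- data.frame(variable = names(counts), n_patients = as.integer(counts),
                    stringsAsFactors = FALSE)
  out[order(-out$n_patients, out$variable), , drop = FALSE]
}

#' Run the iterative harmonization loop
#'
#' Iterates harmonize -> match -> localize against a reference canonical
#' cohort, emitting one audit entry per iteration. Dictionary revisions are
#' external inputs between iterations (the human-in-the-loop contract):
#' supply them either as a list of map sets (one per iteration, last one
#' reused) or as a `revise` callback `function(maps, report, iter)` invoked
#' after each unmatched iteration.
#'
#' @param raw a `raw_tables` object in the source dialect.
#' @param maps initial list with `name_map`, `unit_map`, or a list of such
#'   lists (one per iteration).
#' @param model a fitted `cll_ensemble`.
#' @param reference_cohort canonical `ehr_cohort` for the same patients.
#' @param registry,policy,thresholds,tol as in [match_predictions()].
#' @param max_iters iteration bound.
#' @param revise optional callback revising the dictionaries between
#'   iterations.
#' @return list of class `harmonization_cycle`: `status` ("converged" /
#'   "unconverged"), `iterations`, `final_report`, `audit` (per-iteration
#'   matched fraction and implicated variables).
#' @export
harmonization_cycle <- function(raw, maps, model, reference_cohort,
                                registry = NULL,
                                policy = prediction_point_policy(),
                                thresholds = confidence_thresholds(),
                                tol = 0, max_iters = 5L, revise = NULL) {
  registry <- registry %||% model$registry
  maps_list <- if (!is.null(maps$name_map)) list(maps) else maps
  audit <- list()
  report <- NULL
  cur <- maps_list[[1]]
  for (it in seq_len(max_iters)) {
    cohort <- harmonize(raw, cur$name_map, cur$unit_map,
                        lab_panel = reference_cohort$spec$lab_panel)
    report <- match_predictions(model, reference_cohort, cohort,
                                registry = registry, policy = policy,
                                thresholds = thresholds, tol = tol)
    loc <- localize_discrepancies(report, registry)
    audit[[it]] <- list(iteration = it,
                        matched_fraction = report$matched_fraction,
                        implicated_variables = loc)
    if (report$matched_fraction == 1) {
      return(structure(list(status = "converged", iterations = it,
                            final_report = report, audit = audit),
                       class = "harmonization_cycle"))
    }
    if (!is.null(revise)) cur <- revise(cur, report, it)
    else if (it + 1L <= length(maps_list)) cur <- maps_list[[it + 1L]]
  }
  structure(list(status = "unconverged", iterations = max_iters,
                 final_report = report, audit = audit),
            class = "harmonization_cycle")
}

#' @export
print.harmonization_cycle <- function(x, ...) {
  cat(sprintf("Harmonization cycle: %s after %d iteration(s)\n",
              x$status, x$iterations))
  for (a in x$audit)
    cat(sprintf("  iter %d: matched %.1f%%%s\n", a$iteration,
                100 * a$matched_fraction,
                if (nrow(a$implicated_variables))
                  paste0(" — implicated: ",
                         paste(a$implicated_variables$variable, collapse = ", "))
                else ""))
  invisible(x)
}
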