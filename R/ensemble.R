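# The heterogeneous feature-bagged ensemble. 28 base learners by default
# (13 gradient-boosted tree models with native missing-value routing, 7
# random forests, 4 extremely randomized trees, 2 elastic nets, 2 logistic
# regressions), 20 of which model the composite outcome, 5 the treatment
# outcome and 3 the infection outcome. The soft-vote confidence is the
# unweighted mean of all learners' positive-class probabilities; thresholds
# on that confidence stratify predictions into high-confidence high-risk,
# low-confidence, and high-confidence low-risk bands.

FAMILIES <- c("boosted_trees_native_missing", "random_forest",
              "extremely_randomized_trees", "elastic_net", "logistic")
TARGETS <- c("composite", "treatment", "infection")

#' Ensemble configuration
#'
#' @param n_boosted,n_random_forest,n_extra_trees,n_elastic_net,n_logistic
#'   counts per base-learner family (defaults 13/7/4/2/2).
#' @param outcome_split named integer vector: learners per outcome target;
#'   must sum to the learner count (default 20 composite / 5 treatment /
#'   3 infection).
#' @param bag_fraction fraction of registry features sampled (without
#'   replacement) for each learner's feature bag, in (0, 1].
#' @param seed global seed; per-learner seeds are derived from it.
#' @param hyperparameters optional named list of per-family overrides, e.g.
#'   `list(random_forest = list(num.trees = 100))`.
#' @return object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_boosted = 13L, n_random_forest = 7L,
                            n_extra_trees = 4L, n_elastic_net = 2L,
                            n_logistic = 2L,
                            outcome_split = c(composite = 20L, treatment = 5L,
                                              infection = 3L),
                            bag_fraction = 0.5, seed = 1L,
                            hyperparameters = list()) {
  counts <- c(boosted_trees_native_missing = n_boosted,
              random_forest = n_random_forest,
              extremely_randomized_trees = n_extra_trees,
              elastic_net = n_elastic_net, logistic = n_logistic)
  if (any(counts < 0) || sum(counts) < 1L)
    stop_config("family counts must be nonnegative with at least one learner")
  if (!setequal(names(outcome_split), TARGETS))
    stop_config("outcome_split must name targets {%s}", paste(TARGETS, collapse = ", "))
  if (sum(outcome_split) != sum(counts))
    stop_config("outcome_split (%d) must sum to the learner count (%d)",
                sum(outcome_split), sum(counts))
  if (bag_fraction <= 0 || bag_fraction > 1)
    stop_config("bag_fraction must be in (0, 1]")
  structure(list(counts = counts, outcome_split = outcome_split[TARGETS],
                 bag_fraction = bag_fraction, seed = as.integer(seed),
                 hyperparameters = hyperparameters),
            class = "ensemble_config")
}

# family -> missingness policy; tree boosting routes NA natively, everything
# else is median-imputed on training data.
missing_policy_for <- function(family) {
  if (family == "boosted_trees_native_missing") "native" else "median_impute"
}

learner_specs <- function(config) {
  fams <- rep(names(config$counts), config$counts)
  targs <- rep(TARGETS, config$outcome_split)
  lapply(seq_along(fams), function(i)
    list(index = i, family = fams[i], outcome_target = targs[i],
         seed = derive_seed(config$seed, i),
         missing_policy = missing_policy_for(fams[i])))
}

default_hyper <- function(family) {
  switch(family,
    boosted_trees_native_missing = list(nrounds = 60L, max_depth = 3L,
                                        eta = 0.3, min_child_weight = 2),
    random_forest = list(num.trees = 200L, max.depth = 4L),
    extremely_randomized_trees = list(num.trees = 200L, max.depth = 4L,
                                      num.random.splits = 1L),
    elastic_net = list(alpha = 0.5, s = 0.01),
    logistic = list())
}

fit_one_learner <- function(spec, x, y, bag, hyper) {
  xb <- x[, bag, drop = FALSE]
  medians <- NULL
  if (spec$missing_policy == "median_impute") {
    medians <- apply(xb, 2, stats::median, na.rm = TRUE)
    medians[!is.finite(medians)] <- 0
    xb <- impute_medians(xb, medians)
  }
  fit <- switch(spec$family,
    boosted_trees_native_missing = {
      dtrain <- xgboost::xgb.DMatrix(xb, label = y, missing = NA)
      params <- c(hyper[setdiff(names(hyper), "nrounds")],
                  list(objective = "binary:logistic", nthread = 1L,
                       seed = spec$seed))
      bst <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = hyper$nrounds, verbose = 0)
      list(kind = "xgb", raw = xgboost::xgb.save.raw(bst))
    },
    random_forest = list(kind = "ranger", obj = ranger::ranger(
      x = xb, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = hyper$num.trees, max.depth = hyper$max.depth,
      seed = spec$seed, num.threads = 1L)),
    extremely_randomized_trees = list(kind = "ranger", obj = ranger::ranger(
      x = xb, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = hyper$num.trees, max.depth = hyper$max.depth,
      splitrule = "extratrees", num.random.splits = hyper$num.random.splits,
      seed = spec$seed, num.threads = 1L)),
    elastic_net = list(kind = "glmnet", s = hyper$s, obj = glmnet::glmnet(
      xb, y, family = "binomial", alpha = hyper$alpha, nlambda = 50L)),
    logistic = {
      co <- suppressWarnings(stats::glm.fit(cbind(`(Intercept)` = 1, xb), y,
                                            family = stats::binomial()))$coefficients
      co[is.na(co)] <- 0
      list(kind = "glm", coef = co)
    })
  c(spec, list(bag = bag, medians = medians, fit = fit))
}

impute_medians <- function(xb, medians) {
  for (j in seq_len(ncol(xb))) {
    nas <- is.na(xb[, j])
    if (any(nas)) xb[nas, j] <- medians[j]
  }
  xb
}

predict_one_learner <- function(learner, x) {
  xb <- x[, learner$bag, drop = FALSE]
  if (!is.null(learner$medians)) xb <- impute_medians(xb, learner$medians)
  fit <- learner$fit
  p <- switch(fit$kind,
    xgb = {
      bst <- xgboost::xgb.load.raw(fit$raw)
      as.numeric(predict(bst, xgboost::xgb.DMatrix(xb, missing = NA)))
    },
    ranger = as.numeric(predict(fit$obj, data = xb,
                                num.threads = 1L)$predictions[, "1"]),
    glmnet = as.numeric(predict(fit$obj, xb, s = fit$s, type = "response")),
    glm = as.numeric(stats::plogis(cbind(1, xb) %*% fit$coef)))
  pmin(pmax(p, 0), 1)
}

#' Derive per-target training labels from a cohort
#'
#' Composite: first event of either type within the horizon; treatment /
#' infection: that specific first event within the horizon. Patients excluded
#' by the censoring rule (no event, follow-up shorter than the horizon) or
#' with an event before the prediction point get `usable = FALSE`.
#'
#' @param cohort an `ehr_cohort`.
#' @param policy a [prediction_point_policy()].
#' @return data.frame with `patient_id`, binary `composite`, `treatment`,
#'   `infection`, and logical `usable`.
#' @export
training_labels <- function(cohort, policy = prediction_point_policy()) {
  lab <- label_outcomes(cohort, policy)
  oc <- cohort$outcomes[match(lab$patient_id, cohort$outcomes$patient_id), ]
  within <- lab$label == "positive"
  data.frame(patient_id = lab$patient_id,
             composite = as.integer(within),
             treatment = as.integer(within & oc$event_type == "treatment"),
             infection = as.integer(within & oc$event_type == "infection"),
             usable = lab$label != "excluded",
             stringsAsFactors = FALSE)
}

#' Fit the feature-bagged heterogeneous ensemble
#'
#' Each base learner is trained only on its own random feature bag and its
#' own outcome target. Median imputers (for the non-native-missing families)
#' are fitted on training data only. Training is deterministic under a fixed
#' configuration seed.
#'
#' @param matrix a `feature_matrix` (or plain numeric matrix with column
#'   names).
#' @param labels data.frame as returned by [training_labels()]; rows with
#'   `usable = FALSE` are dropped before fitting.
#' @param config an [ensemble_config()].
#' @return fitted model of class `cll_ensemble`.
#' @seealso [predict.cll_ensemble()], [attribute_risk_factors()]
#' @export
train_ensemble <- function(matrix, labels, config = ensemble_config()) {
  fm <- if (inherits(matrix, "feature_matrix")) matrix else
    structure(list(x = matrix, registry = NULL), class = "feature_matrix")
  x <- fm$x
  if (is.null(colnames(x))) stop_config("feature matrix must have column names")
  if (!is.null(labels$usable)) {
    keep <- labels$usable
    labels <- labels[keep, , drop = FALSE]
    x <- x[match(labels$patient_id, rownames(x)), , drop = FALSE]
  }
  used_targets <- unique(rep(TARGETS, config$outcome_split))
  for (t in used_targets) {
    y <- labels[[t]]
    if (is.null(y)) stop_config("labels lack outcome target '%s'", t)
    if (length(unique(y)) < 2L)
      stop_config("outcome target '%s' has a single class in the training data", t)
  }
  p <- ncol(x)
  bag_size <- max(1L, round(config$bag_fraction * p))
  specs <- learner_specs(config)
  learners <- lapply(specs, function(sp) {
    bag <- with_seed(sp$seed, sort(sample.int(p, bag_size)))
    hyper <- utils::modifyList(default_hyper(sp$family),
                               config$hyperparameters[[sp$family]] %||% list())
    fit_one_learner(sp, x, labels[[sp$outcome_target]], bag, hyper)
  })
  mrep <- missing_representation(fm)
  structure(list(learners = learners, feature_ids = colnames(x),
                 missing_rep = mrep, config = config,
                 registry = fm$registry, n_train = nrow(x)),
            class = "cll_ensemble")
}

# Per-feature "missing representation" used by occlusion attribution:
# counts and one-hot indicators encode absence as 0, everything else as NA.
missing_representation <- function(fm) {
  ids <- colnames(fm$x)
  rep_ <- stats::setNames(rep(NA_real_, length(ids)), ids)
  if (!is.null(fm$registry)) {
    zero <- fm$registry$feature_id[fm$registry$aggregator %in% c("count", "onehot")]
    rep_[zero] <- 0
  }
  rep_
}

#' @export
print.cll_ensemble <- function(x, ...) {
  fam <- table(vapply(x$learners, `[[`, character(1), "family"))
  tg <- table(vapply(x$learners, `[[`, character(1), "outcome_target"))
  cat(sprintf("Feature-bagged soft-voting ensemble: %d learners, %d features, n = %d\n",
              length(x$learners), length(x$feature_ids), x$n_train))
  cat("Families:", paste(sprintf("%s=%d", names(fam), fam), collapse = ", "), "\n")
  cat("Targets: ", paste(sprintf("%s=%d", names(tg), tg), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cll_ensemble <- function(object, ...) {
  print(object)
  bags <- lengths(lapply(object$learners, `[[`, "bag"))
  cat(sprintf("Feature-bag size: %d (fraction %.2f of %d features)\n",
              bags[1], object$config$bag_fraction, length(object$feature_ids)))
  invisible(object)
}

#' Confidence thresholds
#'
#' Soft-vote cutoffs for the confidence bands: `>= t_high` is a
#' high-confidence high-risk prediction, `<= t_low` high-confidence low-risk,
#' anything between is low-confidence. Packaged defaults are 0.58 / 0.28; a
#' recalibrated high cutoff of 0.65 is in clinical use for as-is-missingness
#' cohorts.
#'
#' @param t_high,t_low cutoffs with `0 <= t_low < t_high <= 1`.
#' @return object of class `confidence_thresholds`.
#' @export
confidence_thresholds <- function(t_high = 0.58, t_low = 0.28) {
  if (!(t_low >= 0 && t_low < t_high && t_high <= 1))
    stop_config("need 0 <= t_low < t_high <= 1 (got t_low=%g, t_high=%g)",
                t_low, t_high)
  structure(list(t_high = t_high, t_low = t_low),
            class = "confidence_thresholds")
}

#' Derive confidence thresholds from target band fractions
#'
#' `t_high` is the smallest observed confidence such that the fraction of
#' confidences at or above it does not exceed `frac_high` (upper empirical
#' quantile); `t_low` analogously from below. The defaults mirror the design
#' requirement that 20% of predictions be high-risk with high confidence and
#' 30% low-risk with high confidence.
#'
#' @param confidences numeric vector (length >= 10) of soft-vote confidences.
#' @param frac_high,frac_low target fractions, `0 < frac_high + frac_low <= 1`.
#' @return a [confidence_thresholds()] object.
#' @export
derive_thresholds <- function(confidences, frac_high = 0.20, frac_low = 0.30) {
  n <- length(confidences)
  if (n < 10L) stop_config("need at least 10 confidences (got %d)", n)
  if (!(frac_high >= 0 && frac_low >= 0 && frac_high + frac_low > 0 &&
        frac_high + frac_low <= 1))
    stop_config("need 0 < frac_high + frac_low <= 1")
  cands <- sort(unique(confidences))
  t_high <- 1
  for (c0 in cands) if (mean(confidences >= c0) <= frac_high) { t_high <- c0; break }
  t_low <- 0
  for (c0 in rev(cands)) if (mean(confidences <= c0) <= frac_low) { t_low <- c0; break }
  confidence_thresholds(t_high = t_high, t_low = t_low)
}

confidence_band <- function(confidence, thresholds) {
  ifelse(confidence >= thresholds$t_high, "high_conf_high_risk",
         ifelse(confidence <= thresholds$t_low, "high_conf_low_risk",
                "low_confidence"))
}

#' Predict risk, confidence and band for every patient
#'
#' The soft-vote confidence is the unweighted arithmetic mean of all base
#' learners' positive-class probabilities (outcome-specific learners
#' included). The risk call is high iff confidence >= 0.5. A prediction is
#' returned for every patient regardless of missingness: the method never
#' fails on missing values (100% coverage contract).
#'
#' @param object a fitted `cll_ensemble`.
#' @param newdata a `feature_matrix` or numeric matrix whose columns match
#'   the training registry.
#' @param thresholds a [confidence_thresholds()].
#' @param type `"prediction"` for the per-patient data.frame,
#'   `"learner_matrix"` for the patients x learners probability matrix.
#' @param ... unused.
#' @return data.frame of class `ensemble_prediction` with `patient_id`,
#'   `confidence`, `risk_call`, `band` (or the learner probability matrix).
#' @export
predict.cll_ensemble <- function(object, newdata,
                                 thresholds = confidence_thresholds(),
                                 type = c("prediction", "learner_matrix"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else newdata
  if (is.null(colnames(x))) stop_config("newdata must have feature column names")
  extra <- setdiff(colnames(x), object$feature_ids)
  missing_cols <- setdiff(object$feature_ids, colnames(x))
  if (length(extra) || length(missing_cols))
    stop_config("feature columns do not match the training registry (unknown: %s; absent: %s)",
                if (length(extra)) paste(extra, collapse = ", ") else "-",
                if (length(missing_cols)) paste(missing_cols, collapse = ", ") else "-")
  x <- x[, object$feature_ids, drop = FALSE]
  probs <- vapply(object$learners, predict_one_learner, numeric(nrow(x)), x = x)
  if (nrow(x) == 1L) probs <- matrix(probs, nrow = 1)
  if (type == "learner_matrix") {
    rownames(probs) <- rownames(x)
    return(probs)
  }
  confidence <- rowMeans(probs)
  out <- data.frame(patient_id = rownames(x) %||% as.character(seq_len(nrow(x))),
                    confidence = confidence,
                    risk_call = ifelse(confidence >= 0.5, "high", "low"),
                    band = confidence_band(confidence, thresholds),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ensemble_prediction", "data.frame")
  out
}

#' Signed per-feature risk contributions by occlusion
#'
#' The contribution of feature `f` for a patient is the soft-vote confidence
#' on the original row minus the confidence when `f` is replaced by its
#' missing representation (0 for counts and one-hot indicators, `NA`
#' otherwise). Positive contributions push towards high risk. Deterministic;
#' model-agnostic; reuses the ensemble's own missingness machinery.
#'
#' @param model a fitted `cll_ensemble`.
#' @param newdata a `feature_matrix` or matrix (one or more patients).
#' @return numeric matrix, patients x features, of signed contributions.
#' @export
attribute_risk_factors <- function(model, newdata) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else newdata
  x <- x[, model$feature_ids, drop = FALSE]
  n <- nrow(x)
  p <- ncol(x)
  mrep <- model$missing_rep[model$feature_ids]
  contrib <- matrix(0, n, p, dimnames = list(rownames(x), model$feature_ids))
  # one occluded copy per feature, batched across patients per learner call
  for (i in seq_len(n)) {
    row <- x[i, ]
    occ <- matrix(rep(row, each = p + 1L), nrow = p + 1L,
                  dimnames = list(NULL, colnames(x)))
    occ[cbind(seq_len(p) + 1L, seq_len(p))] <- mrep
    probs <- vapply(model$learners, predict_one_learner, numeric(p + 1L), x = occ)
    conf <- rowMeans(probs)
    contrib[i, ] <- conf[1] - conf[-1]
  }
  contrib
}

#' Top-5 up / top-5 down personalized risk factors
#'
#' Ranks occlusion contributions per patient: up to five features pushing
#' towards high risk (positive contribution) and five pushing towards low
#' risk (negative), each sorted by absolute contribution, ties broken by
#' feature id.
#'
#' @param model a fitted `cll_ensemble`.
#' @param newdata a `feature_matrix` or matrix.
#' @param top number of factors per direction (default 5).
#' @return named list per patient, each with data.frames `up` and `down`
#'   (`feature`, `contribution`).
#' @export
risk_factors <- function(model, newdata, top = 5L) {
  contrib <- attribute_risk_factors(model, newdata)
  apply_one <- function(v) {
    ord <- order(-abs(v), names(v))
    v <- v[ord]
    list(up = {
      u <- v[v > 0][seq_len(min(top, sum(v > 0)))]
      data.frame(feature = names(u), contribution = unname(u),
                 stringsAsFactors = FALSE)
    }, down = {
      d <- v[v < 0][seq_len(min(top, sum(v < 0)))]
      data.frame(feature = names(d), contribution = unname(d),
                 stringsAsFactors = FALSE)
    })
  }
  out <- lapply(seq_len(nrow(contrib)), function(i) apply_one(contrib[i, ]))
  names(out) <- rownames(contrib)
  out
}

#' Serialize / restore a fitted ensemble
#'
#' @param model a `cll_ensemble`.
#' @param path file path.
#' @return `save_ensemble` returns the path invisibly; `load_ensemble` the
#'   restored model.
#' @export
save_ensemble <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) readRDS(path)

#' Export predictions (with personalized risk factors) as CSV
#'
#' One row per patient: risk call, confidence, band, and the top-5 up / down
#' factors serialized as `feature:contribution` pairs — the three outputs a
#' clinician-facing EHR view surfaces.
#'
#' @param predictions an `ensemble_prediction` data.frame.
#' @param path output CSV path.
#' @param factors optional result of [risk_factors()] aligned by patient id.
#' @return invisibly, the path.
#' @export
write_predictions <- function(predictions, path, factors = NULL) {
  out <- as.data.frame(predictions)
  if (!is.null(factors)) {
    fmt <- function(df) paste(sprintf("%s:%.6g", df$feature, df$contribution),
                              collapse = ";")
    out$factors_up <- vapply(factors[out$patient_id],
                             function(f) fmt(f$up), character(1))
    out$factors_down <- vapply(factors[out$patient_id],
                               function(f) fmt(f$down), character(1))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
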