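# Ensemble model: configuration accounting, soft-vote confidence,
# thresholds, bands, occlusion attribution, missingness robustness.

test_that("configuration accounting matches the declared composition", {
  cfg <- ensemble_config()
  expect_equal(sum(cfg$counts), 28L)
  expect_equal(unname(cfg$counts),
               c(13L, 7L, 4L, 2L, 2L))
  expect_equal(unname(cfg$outcome_split), c(20L, 5L, 3L))
  expect_error(ensemble_config(outcome_split = c(composite = 10, treatment = 5,
                                                 infection = 3)),
               "sum")
  expect_error(ensemble_config(bag_fraction = 0), "bag_fraction")
})

test_that("every learner is trained on its own bag of the expected size", {
  fx <- fit_small_model()
  model <- fx$model
  p <- ncol(fx$features$x)
  expect_equal(length(model$learners), 6L)
  bag_size <- max(1L, round(0.5 * p))
  for (l in model$learners) {
    expect_length(l$bag, bag_size)
    expect_true(all(l$bag %in% seq_len(p)))
    if (l$family == "boosted_trees_native_missing") {
      expect_identical(l$missing_policy, "native")
      expect_null(l$medians)
    } else {
      expect_identical(l$missing_policy, "median_impute")
      expect_length(l$medians, bag_size)
    }
  }
})

test_that("a single logistic learner separates a separable toy problem", {
  set.seed(1)
  x <- cbind(f1 = c(rnorm(30, -2), rnorm(30, 2)), f2 = rnorm(60))
  rownames(x) <- sprintf("P%02d", 1:60)
  labels <- data.frame(patient_id = rownames(x),
                       composite = rep(c(0L, 1L), each = 30))
  cfg <- ensemble_config(n_boosted = 0, n_random_forest = 0, n_extra_trees = 0,
                         n_elastic_net = 0, n_logistic = 1,
                         outcome_split = c(composite = 1, treatment = 0,
                                           infection = 0),
                         bag_fraction = 1)
  model <- train_ensemble(x, labels, cfg)
  pred <- predict(model, x)
  expect_true(all(pred$confidence[31:60] > 0.5))
  # single-learner ensemble: confidence equals the learner's probability
  probs <- predict(model, x, type = "learner_matrix")
  expect_identical(unname(probs[, 1]), pred$confidence)
})

test_that("soft-vote confidence is the exact mean of learner probabilities", {
  fx <- fit_small_model()
  probs <- predict(fx$model, fx$features, type = "learner_matrix")
  pred <- predict(fx$model, fx$features)
  expect_lt(max(abs(rowMeans(probs) - pred$confidence)), 1e-12)
  expect_true(all(pred$confidence >= 0 & pred$confidence <= 1))
})

test_that("training is deterministic: same seeds give bit-identical models", {
  fx <- fit_small_model()
  m2 <- train_ensemble(fx$features, training_labels(fx$cohort),
                       small_config(seed = 1))
  expect_identical(serialize(fx$model, NULL), serialize(m2, NULL))
})

test_that("a single-class outcome target is rejected by name", {
  fx <- fit_small_model()
  labels <- training_labels(fx$cohort)
  labels$infection <- 0L
  expect_error(train_ensemble(fx$features, labels, small_config()),
               "infection")
})

test_that("prediction requires matching feature columns", {
  fx <- fit_small_model()
  x <- fx$features$x
  colnames(x)[1] <- "not_a_feature"
  expect_error(predict(fx$model, x), "not_a_feature")
})

test_that("predictions are produced for every missingness pattern", {
  fx <- fit_small_model()
  x <- fx$features$x
  lab_cols <- fx$registry$aggregator %in% c("min", "median", "days_since_latest")
  for (s in 1:5) {
    set.seed(s)
    xm <- x
    mask <- matrix(runif(length(xm)) < 0.7, nrow(xm))
    mask[, !lab_cols] <- FALSE
    xm[mask] <- NA
    pred <- predict(fx$model, xm)
    expect_equal(nrow(pred), nrow(x))
    expect_true(all(is.finite(pred$confidence)))
  }
  # fully missing lab block
  xall <- x
  xall[, lab_cols] <- NA
  pred <- predict(fx$model, xall)
  expect_true(all(is.finite(pred$confidence)))
})

test_that("derived thresholds hit the requested band fractions", {
  conf <- seq(0.005, 0.995, by = 0.01)
  th <- derive_thresholds(conf, frac_high = 0.20, frac_low = 0.30)
  expect_equal(sum(conf >= th$t_high), 20L)
  expect_equal(sum(conf <= th$t_low), 30L)
  # sort-based oracle: t_high is the k-th largest value, k = floor(0.2 n)
  expect_equal(th$t_high, sort(conf, decreasing = TRUE)[20])
  expect_equal(th$t_low, sort(conf)[30])
  expect_equal(derive_thresholds(conf, frac_high = 1.0, frac_low = 0)$t_high,
               min(conf))
  expect_error(derive_thresholds(conf, frac_high = 0.9, frac_low = 0.3),
               "frac")
  expect_error(derive_thresholds(c(0.1, 0.9), 0.2, 0.3), "10")
})

test_that("packaged default thresholds are 0.58 / 0.28 and bands follow them", {
  th <- confidence_thresholds()
  expect_equal(th$t_high, 0.58)
  expect_equal(th$t_low, 0.28)
  x <- structure(list(x = matrix(0.9, 1, 1, dimnames = list("P1", "f"))),
                 class = "feature_matrix")
  expect_error(confidence_thresholds(0.2, 0.5), "t_low")
  # all learners voting 0.9 -> high-confidence high-risk
  bands <- ehrisk:::confidence_band(c(0.9, 0.5, 0.1), th)
  expect_identical(bands, c("high_conf_high_risk", "low_confidence",
                            "high_conf_low_risk"))
})

test_that("raising t_high from 0.58 to 0.65 never adds high-confidence high-risk calls", {
  fx <- fit_small_model()
  pred58 <- predict(fx$model, fx$features, confidence_thresholds(0.58, 0.28))
  pred65 <- predict(fx$model, fx$features, confidence_thresholds(0.65, 0.28))
  expect_lte(sum(pred65$band == "high_conf_high_risk"),
             sum(pred58$band == "high_conf_high_risk"))
})

test_that("occlusion attribution has the sign of a known linear effect", {
  set.seed(2)
  n <- 80
  x <- cbind(risk = c(rnorm(n/2, -1.5), rnorm(n/2, 1.5)), noise = rnorm(n))
  rownames(x) <- sprintf("P%02d", 1:n)
  labels <- data.frame(patient_id = rownames(x),
                       composite = rep(c(0L, 1L), each = n/2))
  cfg <- ensemble_config(n_boosted = 0, n_random_forest = 0, n_extra_trees = 0,
                         n_elastic_net = 0, n_logistic = 1,
                         outcome_split = c(composite = 1, treatment = 0,
                                           infection = 0), bag_fraction = 1)
  model <- train_ensemble(x, labels, cfg)
  row <- matrix(c(2, 0.3), 1, dimnames = list("P01", c("risk", "noise")))
  contrib <- attribute_risk_factors(model, row)
  expect_gt(contrib[1, "risk"], 0)  # positive coefficient, positive value
  # a feature at its missing representation contributes exactly 0
  row0 <- row; row0[1, "noise"] <- NA
  c0 <- attribute_risk_factors(model, row0)
  expect_equal(unname(c0[1, "noise"]), 0)
})

test_that("attribution is deterministic and duplicated patients agree", {
  fx <- fit_small_model()
  x2 <- fx$features$x[c(1, 1, 2), , drop = FALSE]
  rownames(x2) <- c("A", "B", "C")
  contrib <- attribute_risk_factors(fx$model, x2)
  expect_identical(contrib["A", ], contrib["B", ])
  rf <- risk_factors(fx$model, x2)
  expect_identical(rf[["A"]], rf[["B"]])
  expect_lte(nrow(rf[["A"]]$up), 5L)
  expect_lte(nrow(rf[["A"]]$down), 5L)
  if (nrow(rf[["A"]]$up) > 1)
    expect_true(all(diff(abs(rf[["A"]]$up$contribution)) <= 1e-15))
  expect_true(all(rf[["A"]]$up$contribution > 0))
  expect_true(all(rf[["A"]]$down$contribution < 0))
})

test_that("fitted ensembles serialize and restore losslessly", {
  fx <- fit_small_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_ensemble(fx$model, path)
  back <- load_ensemble(path)
  p1 <- predict(fx$model, fx$features)
  p2 <- predict(back, fx$features)
  expect_identical(p1, p2)
})
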