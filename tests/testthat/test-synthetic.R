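# Synthetic-EHR generator: reproducibility, outcome model, missingness
# injection, source dialects.

test_that("an empty cohort spec yields empty tables", {
  co <- generate_cohort(cohort_spec(n_patients = 0, lab_panel = small_panel()))
  expect_equal(nrow(co$baseline), 0L)
  expect_equal(nrow(co$labs), 0L)
  expect_equal(nrow(co$outcomes), 0L)
})

test_that("identical (spec, seed) reproduce identical cohorts byte-for-byte", {
  a <- small_cohort(n = 40, seed = 7)
  b <- small_cohort(n = 40, seed = 7)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- small_cohort(n = 40, seed = 8)
  expect_false(identical(a$outcomes, c2$outcomes))
})

test_that("invalid categorical distributions are rejected naming the field", {
  expect_error(
    cohort_spec(10, baseline_prevalences = list(
      binet = c(A = 0.5, B = 0.4, C = 0.2),
      ighv = c(mutated = 0.7, unmutated = 0.3),
      b2m_high = c(no = 0.9, yes = 0.1),
      fish = c(del17p = 0.2, del11q = 0.2, tri12 = 0.2, normal = 0.2,
               del13q = 0.2),
      ecog = c(`0` = 0.6, `1` = 0.3, `2plus` = 0.1),
      sex = c(female = 0.4, male = 0.6)),
      lab_panel = small_panel()),
    "binet")
  expect_error(cohort_spec(-3), "n_patients")
})

test_that("event timestamps respect follow-up and outcome invariants", {
  co <- small_cohort(n = 150, seed = 3)
  oc <- co$outcomes
  has <- oc$event_type != "none"
  expect_true(all(is.na(oc$event_day[!has])))
  expect_true(all(oc$event_day[has] <= oc$followup_end_day[has]))
  fu <- oc$followup_end_day[match(co$labs$patient_id, oc$patient_id)]
  expect_true(all(co$labs$day <= fu))
})

test_that("with zero covariate effects and equal baselines the two cause clocks are symmetric", {
  # competing exponentials with identical rates: cause is a fair coin
  beta0 <- lapply(cohort_spec(1, lab_panel = small_panel())$outcome_params$beta,
                  function(b) b * 0)
  spec <- cohort_spec(2000, seed = 11, lab_panel = small_panel(1),
                      outcome_params = list(beta = beta0,
                                            treatment_fraction = 0.5),
                      target_rate_2yr = 0.5)
  co <- generate_cohort(spec)
  tab <- table(co$outcomes$event_type)
  n_inf <- tab[["infection"]]; n_trt <- tab[["treatment"]]
  m <- n_inf + n_trt
  expect_lt(abs(n_inf - n_trt), 2 * 1.96 * sqrt(m * 0.25))
})

test_that("missingness injection honours identity, certainty and unknown names", {
  co <- small_cohort(n = 50, seed = 2)
  same <- inject_missingness(co, c(binet = 0, ighv = 0))
  expect_identical(same$baseline, co$baseline)
  expect_identical(same$labs, co$labs)
  all_unknown <- inject_missingness(co, c(binet = 1.0))
  expect_true(all(all_unknown$baseline$binet == "unknown"))
  expect_identical(co$baseline$binet == "unknown",
                   rep(FALSE, 50))  # input untouched
  expect_error(inject_missingness(co, c(not_a_var = 0.5)), "binet")
})

test_that("injected missing fractions concentrate around their probability", {
  co <- generate_cohort(cohort_spec(4000, seed = 5, lab_panel = small_panel(1)))
  set.seed(31)
  out <- inject_missingness(co, c(binet = 0.722))
  expect_lt(abs(mean(out$baseline$binet == "unknown") - 0.722),
            3 * sqrt(0.722 * 0.278 / 4000))
})

test_that("lab-variable missingness drops series wholesale per patient", {
  co <- small_cohort(n = 60, seed = 9)
  v <- co$spec$lab_panel$variable[1]
  set.seed(4)
  out <- inject_missingness(co, stats::setNames(0.5, v))
  before <- unique(co$labs$patient_id[co$labs$variable == v])
  after <- unique(out$labs$patient_id[out$labs$variable == v])
  # survivors keep their full series, dropped patients lose every row
  kept_rows <- out$labs[out$labs$variable == v & out$labs$patient_id %in% after, ]
  orig_rows <- co$labs[co$labs$variable == v & co$labs$patient_id %in% after, ]
  expect_identical(kept_rows$day, orig_rows$day)
  expect_true(length(after) < length(before))
})

test_that("identity dialect renders the canonical export", {
  co <- small_cohort(n = 25, seed = 6)
  rendered <- render_source(co, identity_dialect(co))
  expect_equal(rendered, export_tables(co))
})

test_that("render/harmonize round-trip recovers canonical values to 1e-9", {
  co <- small_cohort(n = 30, seed = 13)
  dial <- random_dialect(co, seed = 21)
  raw <- render_source(co, dial)
  maps <- dialect_maps(dial)
  back <- harmonize(raw, maps$name_map, maps$unit_map,
                    lab_panel = co$spec$lab_panel)
  ord <- function(df) df[order(df$patient_id, df$variable, df$day), ]
  a <- ord(co$labs); b <- ord(back$labs)
  expect_equal(b$value, a$value, tolerance = 1e-9)
  expect_identical(b$variable, a$variable)
  expect_identical(back$baseline$binet[match(co$baseline$patient_id,
                                             back$baseline$patient_id)],
                   co$baseline$binet)
})

test_that("a corrupted unit factor breaks the round-trip only for that variable", {
  co <- small_cohort(n = 20, seed = 14)
  bad_var <- co$spec$lab_panel$variable[3]
  dial <- random_dialect(co, seed = 22,
                         corruption = stats::setNames(1.5, bad_var))
  maps <- dialect_maps(dial)
  back <- harmonize(render_source(co, dial), maps$name_map, maps$unit_map,
                    lab_panel = co$spec$lab_panel)
  ord <- function(df) df[order(df$patient_id, df$variable, df$day), ]
  a <- ord(co$labs); b <- ord(back$labs)
  diff <- abs(a$value - b$value) > 1e-9
  expect_true(all(a$variable[diff] == bad_var))
  expect_true(any(diff))
  clean <- a$variable != bad_var
  expect_equal(b$value[clean], a$value[clean], tolerance = 1e-9)
})

test_that("uncovered variables are reported by name when rendering", {
  co <- small_cohort(n = 10, seed = 15)
  dial <- identity_dialect(co)
  dial$name_scramble <- dial$name_scramble[-1]
  expect_error(render_source(co, dial), names(baseline_variables())[1])
})

test_that("cohort CSV export writes the four tables plus the truth file", {
  co <- small_cohort(n = 12, seed = 16)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_setequal(list.files(dir),
                  c("baseline.csv", "labs.csv", "cultures.csv",
                    "outcomes.csv", "truth.json"))
  raw <- read_raw_tables(dir)
  expect_equal(nrow(raw$outcomes), 12L)
  # latent risk never leaks into the exported tables
  expect_false(any(grepl("latent", unlist(lapply(raw, names)))))
})
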