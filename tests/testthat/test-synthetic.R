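test_that("generator is a pure function of its parameters", {
  a <- sample_cohort(generator_params(n_patients = 200, seed = 42))
  b <- sample_cohort(generator_params(n_patients = 200, seed = 42))
  expect_equal(a$patients, b$patients)
  expect_equal(a$events, b$events)
  c <- sample_cohort(generator_params(n_patients = 200, seed = 43))
  expect_false(isTRUE(all.equal(a$patients, c$patients)))
})

test_that("zero event probabilities yield an event-free cohort", {
  p <- generator_params(n_patients = 50, seed = 1, early_sae_prob = 0,
                        event_probs = c(neutropenic_fever = 0,
                                        transfusion = 0,
                                        mild_renal_impairment = 0,
                                        nausea_diarrhea = 0))
  co <- sample_cohort(p)
  expect_equal(nrow(co$events), 0)
})

test_that("large-cohort event rates converge to the configured probabilities", {
  p <- generator_params(n_patients = 10000, seed = 7)
  co <- sample_cohort(p)
  n <- p$n_patients
  for (t in names(p$event_probs)) {
    # early events share a type vocabulary with the late ones; count only
    # post-window occurrences against the configured late-event rate
    # (nausea/diarrhea is never an early event and keeps its full support)
    ev <- co$events[co$events$event_type == t, ]
    if (t != "nausea_diarrhea") ev <- ev[ev$onset_day >= 3, ]
    obs <- dplyr::n_distinct(ev$patient_id)
    pe <- p$event_probs[[t]]
    expect_lt(abs(obs / n - pe), 3 * sqrt(pe * (1 - pe) / n))
  }
  fs <- first_sae_day(co)$first_sae_day
  expect_equal(sum(fs %in% 3:4, na.rm = TRUE), 0)  # bimodality gap
  p_early <- mean(fs < 3, na.rm = FALSE) # NA first-SAE is not early
  obs_early <- sum(!is.na(fs) & fs < 3) / n
  expect_lt(abs(obs_early - 0.036), 3 * sqrt(0.036 * 0.964 / n))
})

test_that("planted occurrence effects are recovered by a logistic fit", {
  eff <- planted_effect("creatinine_mg_dl", "mild_renal_impairment", 2.0)
  co <- sample_cohort(generator_params(n_patients = 2000, seed = 3,
                                       effect_spec = eff,
                                       missingness_rate = 0))
  ds <- make_ml_dataset(co, "mri", "mi_extended")
  fit <- stats::glm(label ~ creatinine_mg_dl, data = ds, family = binomial)
  ci <- stats::confint.default(fit)["creatinine_mg_dl", ]
  expect_gt(2.0, ci[1])
  expect_lt(2.0, ci[2])
})

test_that("without planted effects, outcomes are independent of covariates", {
  co <- sample_cohort(generator_params(n_patients = 4000, seed = 5,
                                       missingness_rate = 0))
  ds <- make_ml_dataset(co, "fever", "clinical")
  hi_cr <- ds$hemoglobin_g_dl > median(ds$hemoglobin_g_dl)
  pval <- suppressWarnings(
    stats::chisq.test(table(hi_cr, ds$label)))$p.value
  expect_gt(pval, 0.0027)  # not significant at the 3-SD level
})

test_that("model datasets follow the endpoint and feature-set contracts", {
  pats <- dplyr::bind_rows(purrr::map(1:10, function(i) {
    toy_patient(sprintf("M%02d", i))
  }))
  evs <- dplyr::bind_rows(
    purrr::map(1:4, ~toy_event(sprintf("M%02d", .x), "neutropenic_fever",
                               onset = 8L + .x)),
    toy_event("M05", "transfusion", 11L),
    toy_event("M06", "neutropenic_fever", 1L))  # early: excluded
  co <- new_cohort(pats, evs)

  ds <- make_ml_dataset(co, "fever", "clinical")
  expect_equal(nrow(ds), 9)                      # early patient dropped
  expect_false("M06" %in% ds$patient_id)
  expect_equal(sum(ds$label), 4)
  feat <- setdiff(names(ds), c("patient_id", "label", "onset_day"))
  expect_length(feat, 7)
  expect_true(all(is.na(ds$onset_day[ds$label == 0])))
  expect_equal(sort(ds$onset_day[ds$label == 1]), 9:12)

  expect_length(setdiff(names(make_ml_dataset(co, "fever", "mi_extended")),
                        c("patient_id", "label", "onset_day")), 16)
  expect_length(setdiff(names(make_ml_dataset(co, "fever", "longitudinal")),
                        c("patient_id", "label", "onset_day")), 26)
  # excluding early patients changes rows, never columns
  expect_equal(setdiff(names(make_ml_dataset(co, "any_sae", "clinical")),
                       c("patient_id", "label", "onset_day")), feat)
  expect_error(make_ml_dataset(co, "relapse"), "arg")
})

test_that("degenerate generator parameters are rejected", {
  expect_error(generator_params(early_sae_prob = 1.2),
               class = "scm_parameter_error")
  bad_onsets <- list(neutropenic_fever = list(min = 9L, max = 5L, median = 7,
                                              p = 0.5))
  expect_error(generator_params(onset_models = modifyList(
    generator_params()$onset_models, bad_onsets)),
    class = "scm_parameter_error")
})
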