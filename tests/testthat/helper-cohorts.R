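# In-code fixtures: toy patients with fully specified timelines, and random
# small cohorts for property tests.

toy_patient <- function(id = "T1", offset = -1L, regimen = "cyclo_4000",
                        leuk_on = 7L, leuk_dur = 4L, scc = 12L,
                        scc_dur = 1L, success = TRUE, post = 1L) {
  tibble::tibble(
    patient_id = id, admission_offset = as.integer(offset),
    regimen = regimen,
    therapy_duration_days = regimen_durations()[[regimen]],
    leukopenia_onset_day = leuk_on, leukopenia_duration_days = leuk_dur,
    scc_start_day = if (success) as.integer(scc) else NA_integer_,
    scc_duration_days = if (success) as.integer(scc_dur) else NA_integer_,
    scc_success = success,
    post_scc_days = if (success) as.integer(post) else NA_integer_,
    age_years = 60L, sex = "M", creatinine_mg_dl = 0.9, ldh_u_l = 200,
    hemoglobin_g_dl = 11, platelets_per_nl = 220, crp_mg_l = 5,
    calcium_mmol_l = 2.3, albumin_g_dl = 4, prior_ce_therapy = FALSE,
    prior_lines = 1L, full_dose_flag = TRUE, cyclo_flag = TRUE,
    ce_flag = FALSE, etoposide_flag = FALSE, gcsf_dose_flag = TRUE,
    day3_creatinine_mg_dl = 0.9, day3_ldh_u_l = 200,
    day3_hemoglobin_g_dl = 10.5, day3_platelets_per_nl = 180,
    day3_crp_mg_l = 6, day5_creatinine_mg_dl = 0.9, day5_ldh_u_l = 200,
    day5_hemoglobin_g_dl = 10, day5_platelets_per_nl = 150,
    day5_crp_mg_l = 8)
}

toy_event <- function(id, type = "neutropenic_fever", onset = 9L,
                      grade = 3L, hosp = TRUE) {
  tibble::tibble(patient_id = id, event_type = type,
                 onset_day = as.integer(onset),
                 ctcae_grade = as.integer(grade),
                 requires_hospitalization = hosp, germ_detected = NA)
}

no_events <- function() toy_event(character(0))[0, ]

# random small cohort exercising edge cases: failed collections, early
# events, events after the nominal post-collection tail, patients without
# any events
random_cohort <- function(n, seed) {
  withr::with_seed(seed, {
    pats <- purrr::map(seq_len(n), function(i) {
      success <- runif(1) < 0.85
      toy_patient(
        id = sprintf("R%02d", i),
        offset = sample(-4:0, 1),
        regimen = sample(names(regimen_durations()), 1),
        scc = sample(10:19, 1), scc_dur = sample(1:3, 1),
        success = success, post = sample(0:3, 1))
    }) |> dplyr::bind_rows()
    evs <- purrr::map(seq_len(n), function(i) {
      k <- sample(0:3, 1)
      if (k == 0) return(NULL)
      toy_event(sprintf("R%02d", i),
                type = sample(event_types(), k, replace = TRUE),
                onset = sample(0:18, k, replace = TRUE),
                grade = sample(2:4, k, replace = TRUE),
                hosp = runif(k) < 0.7)
    }) |> dplyr::bind_rows()
    if (is.null(evs) || nrow(evs) == 0) evs <- no_events()
    new_cohort(pats, evs)
  })
}

# independent bed-day oracle: day-by-day occupancy enumeration
occupancy_bed_days <- function(intervals, days = -10:60) {
  if (nrow(intervals) == 0) return(0L)
  sum(vapply(split(intervals, intervals$patient_id), function(iv) {
    sum(vapply(days, function(d) {
      any(iv$start_day <= d & d <= iv$end_day)
    }, logical(1)))
  }, numeric(1)))
}
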