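test_that("persistence round-trips losslessly in both formats", {
  co <- new_cohort(
    dplyr::bind_rows(toy_patient("A1"), toy_patient("A2", offset = -3L,
                                                    regimen = "etoposide_alone")),
    toy_event("A1", onset = 9L))
  jf <- withr::local_tempfile(fileext = ".json")
  write_cohort(co, jf, "json")
  back <- read_cohort(jf, "json")
  expect_equal(back$patients, co$patients)
  expect_equal(back$events, co$events)
  expect_equal(back$provenance, co$provenance)

  # synthetic cohort with missing labs: missingness must survive the trip
  sy <- sample_cohort(generator_params(n_patients = 60, seed = 11,
                                       missingness_rate = 0.05))
  expect_gt(sum(is.na(sy$patients$crp_mg_l)), 0)
  cd <- withr::local_tempdir()
  write_cohort(sy, cd, "csv")
  back_csv <- read_cohort(cd, "csv")
  expect_equal(back_csv$patients, sy$patients)
  expect_equal(back_csv$events, sy$events)

  # json -> csv -> json is the identity
  jf2 <- withr::local_tempfile(fileext = ".json")
  write_cohort(back_csv, jf2, "json")
  again <- read_cohort(jf2, "json")
  expect_equal(again$patients, sy$patients)
  expect_equal(again$events, sy$events)
  expect_equal(again$seed, sy$seed)
})

test_that("schema and invariant violations are rejected with context", {
  p <- toy_patient("B1")
  expect_error(new_cohort(p[setdiff(names(p), "regimen")], no_events()),
               "regimen", class = "scm_schema_error")
  bad <- dplyr::mutate(p, therapy_duration_days = 3L)  # cyclo_4000 takes 2 d
  expect_error(new_cohort(bad, no_events()), "B1",
               class = "scm_validation_error")
  expect_error(new_cohort(dplyr::bind_rows(p, p), no_events()),
               "duplicated", class = "scm_validation_error")
  expect_error(new_cohort(dplyr::mutate(p, scc_start_day = 25L), no_events()),
               "\\[10, 19\\]", class = "scm_validation_error")
  expect_error(new_cohort(p, toy_event("B1", onset = 40L)),
               "onset_day", class = "scm_validation_error")
  expect_error(new_cohort(p, toy_event("ZZ", onset = 5L)),
               "unknown patient", class = "scm_validation_error")
})

test_that("first SAE day is the minimum hospitalizing onset", {
  co <- new_cohort(
    dplyr::bind_rows(toy_patient("C1"), toy_patient("C2"),
                     toy_patient("C3")),
    dplyr::bind_rows(
      toy_event("C1", "neutropenic_fever", 9L),
      toy_event("C1", "transfusion", 11L),
      toy_event("C2", "nausea_diarrhea", 2L, grade = 2L, hosp = FALSE)))
  fs <- first_sae_day(co)
  expect_equal(fs$first_sae_day[fs$patient_id == "C1"], 9L)
  expect_true(is.na(fs$first_sae_day[fs$patient_id == "C2"]))  # not severe
  expect_true(is.na(fs$first_sae_day[fs$patient_id == "C3"]))  # no events

  # invariant to event ordering
  for (s in 1:5) {
    perm <- co
    perm$events <- co$events[withr::with_seed(s, sample(nrow(co$events))), ]
    expect_equal(first_sae_day(perm), fs)
  }
})

test_that("early-SAE window is half-open at integer day resolution", {
  mk <- function(onset, offset = 0L) {
    new_cohort(toy_patient("D1", offset = offset),
               toy_event("D1", onset = onset))
  }
  expect_true(is_early_sae(mk(2L))$early_sae)    # day 2 inside [0, 3)
  expect_false(is_early_sae(mk(3L))$early_sae)   # boundary outside
  expect_false(is_early_sae(mk(5L))$early_sae)
  # anchoring at hospital admission shifts the window by the admission gap
  co <- mk(1L, offset = -2L)
  expect_true(is_early_sae(co, anchor = "therapy_start")$early_sae)
  expect_false(is_early_sae(co, anchor = "admission")$early_sae)
})
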