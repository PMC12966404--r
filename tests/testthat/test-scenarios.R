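test_that("hand-computed toy timelines give the expected bed-days", {
  # admission day -1, therapy days 0-1, fever day 9, collection day 12,
  # one observed post-collection day
  co <- new_cohort(toy_patient("T1"), toy_event("T1", onset = 9L))

  cur <- bed_days(co, scenario_spec("current"))
  expect_equal(cur$total_bd, 15)            # [-1, 13]
  expect_equal(cur$component_bd[["pre_therapy"]], 1)
  expect_equal(cur$component_bd[["post_scc"]], 1)

  se2 <- bed_days(co, scenario_spec("empirical", "X2"))
  expect_equal(se2$total_bd, 5)             # [9, 13]
  sb2 <- bed_days(co, scenario_spec("best", "X2"))
  expect_equal(sb2$total_bd, 4)             # fever shifted to day 10

  # fever at day 0 cannot shift below therapy start in the worst case
  co0 <- new_cohort(toy_patient("T2"), toy_event("T2", onset = 0L))
  sh <- apply_scenario_events(co0, scenario_spec("worst", "X2"))
  expect_equal(sh$events$onset_day, 0L)

  # no-SAE patient, collection days 12-13: day-5 policy holds the patient
  # from day 5 through the collection block
  co5 <- new_cohort(toy_patient("T3", scc_dur = 2L, post = 0L), no_events())
  d5 <- bed_days(co5, scenario_spec("day5", "X2"))
  expect_equal(d5$total_bd, 9)              # [5, 13]
  expect_equal(bed_days(co5, scenario_spec("empirical", "X3"))$total_bd, 0)
})

test_that("scenario event modification shifts only neutropenic fever", {
  co <- new_cohort(toy_patient("U1"),
                   dplyr::bind_rows(toy_event("U1", onset = 9L),
                                    toy_event("U1", "transfusion", 11L)))
  w <- apply_scenario_events(co, scenario_spec("worst", "X1"))
  expect_equal(w$events$onset_day[w$events$event_type ==
                                    "neutropenic_fever"], 8L)
  expect_equal(w$events$onset_day[w$events$event_type == "transfusion"], 11L)
  e <- apply_scenario_events(co, scenario_spec("empirical", "X1"))
  expect_equal(e$events, co$events)
  o <- apply_scenario_events(
    co, scenario_spec("empirical", "X3",
                      outpatient_manageable = "transfusion"))
  expect_false(any(o$events$requires_hospitalization[
    o$events$event_type == "transfusion"]))
})

test_that("bed-day accounting matches day-by-day occupancy on random cohorts", {
  fams <- list(scenario_spec("current"), scenario_spec("day5", "X2"),
               scenario_spec("worst", "X1"), scenario_spec("empirical", "X3"),
               scenario_spec("best", "X2"))
  for (s in 1:60) {
    co <- random_cohort(n = sample(1:5, 1) + 0, seed = 1000 + s)
    spec <- fams[[(s %% length(fams)) + 1]]
    iv <- hospitalization_intervals(co, spec)
    res <- bed_days(co, spec)
    expect_equal(res$total_bd, occupancy_bed_days(iv))
    expect_equal(sum(res$component_bd), res$total_bd)  # conservation
  }
})

test_that("sub-model and fever-shift monotonicity hold patientwise", {
  for (s in 1:25) {
    co <- random_cohort(n = 5, seed = 2000 + s)
    for (fam in c("empirical", "best", "worst")) {
      b1 <- bed_days(co, scenario_spec(fam, "X1"))$per_patient$bd
      b2 <- bed_days(co, scenario_spec(fam, "X2"))$per_patient$bd
      b3 <- bed_days(co, scenario_spec(fam, "X3"))$per_patient$bd
      expect_true(all(b1 >= b2 & b2 >= b3))
    }
    for (sub in c("X1", "X2")) {
      bb <- bed_days(co, scenario_spec("best", sub))$per_patient$bd
      be <- bed_days(co, scenario_spec("empirical", sub))$per_patient$bd
      bw <- bed_days(co, scenario_spec("worst", sub))$per_patient$bd
      expect_true(all(bb <= be & be <= bw))
    }
    # every outpatient interval lies inside the observed inpatient course
    cur <- hospitalization_intervals(co, scenario_spec("current"))
    for (spec in list(scenario_spec("day5", "X1"),
                      scenario_spec("worst", "X2"),
                      scenario_spec("best", "X3"))) {
      iv <- hospitalization_intervals(co, spec)
      j <- dplyr::left_join(iv, cur, by = "patient_id",
                            suffix = c("", "_cur"))
      expect_true(all(j$start_day >= j$start_day_cur &
                        j$end_day <= j$end_day_cur))
    }
  }
})

test_that("normalization is the ratio to the observed course", {
  co <- new_cohort(toy_patient("N1"), toy_event("N1", onset = 9L))
  ref <- bed_days(co, scenario_spec("current"))
  same <- normalize_bed_days(ref, ref)
  expect_equal(same$normalized_fraction, 1.0)
  r <- bed_days(co, scenario_spec("empirical", "X2"))
  r$total_bd <- 440L; ref2 <- ref; ref2$total_bd <- 1754L
  expect_equal(round(normalize_bed_days(r, ref2)$normalized_fraction, 4),
               0.2509)
  half <- ref; half$total_bd <- ref$total_bd / 2
  expect_equal(normalize_bed_days(half, ref)$normalized_fraction, 0.5)
  zero <- ref; zero$total_bd <- 0L
  expect_error(normalize_bed_days(r, zero), "zero")
})

test_that("bootstrap interval behaves on degenerate and fixture cohorts", {
  pats <- dplyr::bind_rows(purrr::map(1:6, function(i) {
    toy_patient(sprintf("Z%02d", i))
  }))
  evs <- dplyr::bind_rows(purrr::map(1:6, function(i) {
    toy_event(sprintf("Z%02d", i), onset = 9L)
  }))
  ident <- new_cohort(pats, evs)
  ci <- bootstrap_ci(ident, scenario_spec("empirical", "X2"),
                     n_boot = 200, seed = 2)
  expect_equal(ci$ci_low, ci$ci_high)   # identical patients: zero width

  fx <- build_fixture_cohort()
  ci_fx <- bootstrap_ci(fx, scenario_spec("empirical", "X2"),
                        n_boot = 400, seed = 3)
  expect_lte(ci_fx$ci_low, ci_fx$fraction)
  expect_gte(ci_fx$ci_high, ci_fx$fraction)
})

test_that("rank comparison separates scenarios and is null on identity", {
  co <- random_cohort(40, seed = 77)
  same <- compare_scenarios(co, scenario_spec("current"),
                            scenario_spec("current"))
  expect_gt(same$p_value, 0.99)
  diff <- compare_scenarios(co, scenario_spec("current"),
                            scenario_spec("empirical", "X3"))
  expect_lt(diff$p_value, 0.001)
})

test_that("the scenario grid is ordered and normalized", {
  fx <- build_fixture_cohort()
  suite <- scenario_suite(fx, n_boot = 50, seed = 1)
  expect_equal(suite$fraction[suite$label == "Current"], 1.0)
  tot <- function(lbl) suite$total_bd[suite$label == lbl]
  for (x in c("1", "2")) {
    expect_true(tot("Current") >= tot(paste0("S5", x)) &&
                  tot(paste0("S5", x)) >= tot(paste0("SW", x)) &&
                  tot(paste0("SW", x)) >= tot(paste0("SE", x)) &&
                  tot(paste0("SE", x)) >= tot(paste0("SB", x)))
  }
  for (fam in c("SE", "SB")) {
    expect_true(tot(paste0(fam, "1")) >= tot(paste0(fam, "2")) &&
                  tot(paste0(fam, "2")) >= tot(paste0(fam, "3")))
  }
})
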