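# Deterministic reconstruction of the published 109-patient cohort summary.
# Only marginals are printed; the joint structure (which patients co-experience
# events) is under-determined and is resolved by a fixed greedy assignment so
# that the build is reproducible byte-for-byte.

#' Published cohort marginal constraints
#'
#' The printed cohort summary transcribed into a constraint set: cohort size,
#' regimen counts, admission-to-therapy gaps, leukopenia onset/duration,
#' collection timing and success, per-event patient counts with onset
#' median/min/max, and the severe-adverse-event tallies. Where the summary
#' prints only bins plus a median, the constraint set additionally fixes a
#' deterministic value-level resolution consistent with those bins and
#' medians (fields suffixed `_counts`).
#'
#' @return A list of class `scm_constraints`.
#' @export
default_constraints <- function() {
  con <- list(
    cohort_size = 109L,
    regimen_counts = c(etoposide_alone = 10L, etoposide_cyclo = 44L,
                       cyclo_4000 = 55L),
    admission_offset_counts = c(`0` = 50L, `-1` = 51L, `-2` = 3L,
                                `-3` = 3L, `-4` = 2L),
    admission_offset_bins = c(`0-1` = 101L, `2-4` = 8L),
    leukopenia_count = 100L,
    leukopenia_onset_counts = c(`6` = 20L, `7` = 45L, `8` = 26L,
                                `9` = 8L, `10` = 1L),
    leukopenia_onset_bins = c(`6-8` = 91L, `9+` = 9L),
    leukopenia_onset_median = 7,
    leukopenia_duration_counts = c(`1` = 5L, `2` = 13L, `3` = 15L,
                                   `4` = 30L, `5` = 22L, `6` = 8L,
                                   `7` = 5L, `8` = 2L),
    leukopenia_duration_bins = c(`1-3` = 33L, `4-5` = 52L, `6-8` = 15L),
    leukopenia_duration_median = 4,
    scc_interval_counts = c(`10` = 8L, `11` = 12L, `12` = 16L, `13` = 30L,
                            `14` = 17L, `15` = 10L, `16` = 6L, `17` = 4L,
                            `18` = 2L, `19` = 1L),
    scc_interval_bins = c(`10-12` = 36L, `13-15` = 57L, `16-19` = 13L),
    scc_interval_median = 13,
    scc_duration_counts = c(`1` = 77L, `2` = 27L, `3` = 2L),
    scc_success_count = 106L,
    event_rates = c(neutropenic_fever = 59L, transfusion = 28L,
                    mild_renal_impairment = 12L, nausea_diarrhea = 24L,
                    aki = 1L),
    event_onset_summaries = list(
      neutropenic_fever = list(median = 9, min = 1, max = 12),
      transfusion = list(median = 11, min = 9, max = 14),
      mild_renal_impairment = list(median = 10, min = 1, max = 14),
      nausea_diarrhea = list(median = 4, min = 1, max = 16),
      aki = list(median = 0, min = 0, max = 0)),
    germ_detected_count = 26L,
    early_sae_count = 4L,
    any_sae_count = 75L,
    ctcae3_count = 65L,
    any_ae_count = 81L,
    late_onset_floor_day = 5L)
  structure(con, class = "scm_constraints")
}

#' Check internal consistency of a constraint set
#'
#' Verifies that bin and value counts sum to their stated denominators and
#' that no count exceeds the cohort size.
#'
#' @param constraints An `scm_constraints` list.
#' @return The constraints, invisibly; errors describing the violated sum
#'   otherwise.
#' @export
validate_constraints <- function(constraints) {
  con <- constraints
  chk <- function(ok, what) {
    if (!ok) abort(sprintf("inconsistent constraints: %s", what),
                   class = "scm_constraint_error")
  }
  n <- con$cohort_size
  chk(sum(con$regimen_counts) == n, "regimen counts must sum to cohort size")
  chk(sum(con$admission_offset_counts) == n,
      "admission offsets must sum to cohort size")
  chk(sum(con$admission_offset_bins) == n,
      "admission offset bins must sum to cohort size")
  chk(sum(con$leukopenia_onset_counts) == con$leukopenia_count,
      "leukopenia onsets must sum to leukopenia count")
  chk(sum(con$leukopenia_duration_counts) == con$leukopenia_count,
      "leukopenia durations must sum to leukopenia count")
  chk(sum(con$scc_interval_counts) == con$scc_success_count,
      "collection intervals must sum to success count")
  chk(sum(con$scc_duration_counts) == con$scc_success_count,
      "collection durations must sum to success count")
  chk(all(con$event_rates <= n), "event rates must not exceed cohort size")
  chk(con$any_sae_count <= n && con$ctcae3_count <= con$any_sae_count,
      "SAE tallies must be nested within cohort size")
  chk(con$any_ae_count >= con$any_sae_count,
      "any-AE count must be >= any-SAE count")
  chk(con$early_sae_count <= con$any_sae_count,
      "early-SAE count must be <= any-SAE count")
  invisible(constraints)
}

# Deterministic onset multiset: fill the median positions, then spread the
# remaining values linearly between the attainable minimum and maximum so the
# printed median, min and max are met exactly. `early_vals` are pre-assigned
# onsets below the bimodality gap; all other values respect `floor_day`.
make_onset_multiset <- function(n, med, lo, hi, early_vals = integer(),
                                floor_day = lo) {
  e <- length(early_vals)
  n_rest <- n - e
  fail <- function(msg) abort(sprintf("infeasible onset constraints: %s", msg),
                              class = "scm_constraint_error")
  if (n_rest < 0) fail("more early onsets than events")
  if (n_rest == 0) return(list(early = sort(early_vals), rest = integer()))
  lo_rest <- max(lo, floor_day)
  m1 <- floor((n + 1) / 2)
  m2 <- ceiling((n + 1) / 2)
  if (m1 <= e) fail("median falls among early onsets")
  k1 <- m1 - e
  k2 <- m2 - e
  rest <- integer(n_rest)
  rest[k1] <- as.integer(floor(med))
  rest[k2] <- as.integer(ceiling(med))
  if (med < lo_rest || med > hi) fail("median outside support")
  if (k1 > 1) {
    rest[seq_len(k1 - 1)] <-
      as.integer(round(seq(lo_rest, med, length.out = k1)))[seq_len(k1 - 1)]
  }
  if (k2 < n_rest) {
    up <- as.integer(round(seq(med, hi, length.out = n_rest - k2 + 1)))[-1]
    rest[(k2 + 1):n_rest] <- up
  } else if (hi > max(rest, early_vals)) {
    fail("maximum not attainable while holding the median")
  }
  list(early = sort(as.integer(early_vals)), rest = rest)
}

expand_counts <- function(counts) {
  rep(as.integer(names(counts)), times = counts)
}

#' Build the deterministic fixture cohort
#'
#' Constructs a cohort whose summary statistics reproduce every constraint in
#' `constraints` exactly: counts per regimen and bin, per-event patient
#' counts, onset multisets attaining the printed median/min/max, early-SAE,
#' any-SAE and CTCAE>=3 patient tallies, and the collection-success count.
#' The joint assignment is a fixed greedy scheme (patients sorted by id,
#' events allocated in type order with overlaps chosen so the union tallies
#' are hit exactly); patient-level covariates carry no printed constraints
#' and are drawn from the synthetic covariate models under `seed`.
#'
#' @param constraints An `scm_constraints` list; see [default_constraints()].
#' @param seed Integer seed for the covariate draw (default 0).
#' @return A validated `scm_cohort` with provenance `"fixture"`. Re-running
#'   with the same seed returns an identical cohort.
#' @export
build_fixture_cohort <- function(constraints = default_constraints(),
                                 seed = 0) {
  con <- validate_constraints(constraints)
  n <- con$cohort_size
  ids <- sprintf("P%03d", seq_len(n))
  fail <- function(msg) abort(sprintf("infeasible constraints: %s", msg),
                              class = "scm_constraint_error")

  regimen <- rep(names(con$regimen_counts), times = con$regimen_counts)
  therapy_dur <- unname(regimen_durations()[regimen])
  offsets <- expand_counts(con$admission_offset_counts)

  n_leuk <- con$leukopenia_count
  leuk_onset <- rep(NA_integer_, n)
  leuk_dur <- rep(NA_integer_, n)
  leuk_onset[seq_len(n_leuk)] <- sort(expand_counts(con$leukopenia_onset_counts))
  leuk_dur[seq_len(n_leuk)] <- sort(expand_counts(con$leukopenia_duration_counts))

  n_succ <- con$scc_success_count
  scc_success <- c(rep(TRUE, n_succ), rep(FALSE, n - n_succ))
  scc_start <- rep(NA_integer_, n)
  scc_dur <- rep(NA_integer_, n)
  post_scc <- rep(NA_integer_, n)
  scc_start[seq_len(n_succ)] <- sort(expand_counts(con$scc_interval_counts))
  scc_dur[seq_len(n_succ)] <- sort(expand_counts(con$scc_duration_counts))
  post_scc[seq_len(n_succ)] <- ifelse(seq_len(n_succ) %% 2 == 0, 2L, 1L)

  # --- event-to-patient assignment -------------------------------------
  n_sae <- con$any_sae_count
  rates <- con$event_rates
  summ <- con$event_onset_summaries
  floor_day <- con$late_onset_floor_day

  # early slots: one AKI at admission when available, then alternating
  # fever / renal events at the smallest printed onsets inside the window
  k_early <- con$early_sae_count
  slots <- list()
  if (k_early > 0 && isTRUE(rates[["aki"]] >= 1)) {
    slots[[1]] <- list(type = "aki", onset = 0L)
  }
  d <- 0L
  while (length(slots) < k_early) {
    added <- FALSE
    for (t in c("neutropenic_fever", "mild_renal_impairment")) {
      if (length(slots) >= k_early) break
      o <- summ[[t]]$min + d
      n_t <- sum(vapply(slots, function(s) s$type == t, logical(1)))
      if (o <= 2 && o >= summ[[t]]$min && n_t <= d && rates[[t]] > n_t) {
        slots[[length(slots) + 1]] <- list(type = t, onset = as.integer(o))
        added <- TRUE
      }
    }
    d <- d + 1L
    if (!added && d > 2L) fail("cannot place the required early-SAE onsets")
  }
  early_type <- vapply(slots, `[[`, character(1), "type")
  early_onset <- vapply(slots, `[[`, integer(1), "onset")
  early_ids <- ids[seq_along(slots)]

  n_nf <- rates[["neutropenic_fever"]]
  n_tr <- rates[["transfusion"]]
  n_mri <- rates[["mild_renal_impairment"]]
  if (n_nf > n_sae || n_tr > n_sae || n_mri > n_sae) {
    fail("a single event rate exceeds the any-SAE count")
  }
  nf_ids <- ids[seq_len(n_nf)]
  tr_ids <- ids[(n_sae - n_tr + 1):n_sae]
  uncovered <- setdiff(ids[seq_len(n_sae)], c(nf_ids, tr_ids))
  mri_fixed <- early_ids[early_type == "mild_renal_impairment"]
  mri_ids <- unique(c(mri_fixed, uncovered,
                      setdiff(ids[seq_len(n_sae)], c(mri_fixed, uncovered))))
  mri_ids <- mri_ids[seq_len(n_mri)]
  covered <- unique(c(nf_ids, tr_ids, mri_ids,
                      early_ids[early_type == "aki"]))
  if (length(setdiff(ids[seq_len(n_sae)], covered)) > 0 ||
      length(covered) != n_sae) {
    fail("event rates cannot cover the any-SAE count exactly")
  }

  build_events <- function(type, id_set, req_hosp, grade) {
    e_ids <- early_ids[early_type == type]
    e_ons <- early_onset[early_type == type]
    ms <- make_onset_multiset(
      n = length(id_set), med = summ[[type]]$median,
      lo = summ[[type]]$min, hi = summ[[type]]$max,
      early_vals = e_ons,
      floor_day = if (req_hosp) floor_day else summ[[type]]$min)
    rest_ids <- sort(setdiff(id_set, e_ids))
    tibble(patient_id = c(e_ids, rest_ids),
           event_type = type,
           onset_day = c(e_ons, ms$rest),
           ctcae_grade = grade,
           requires_hospitalization = req_hosp,
           germ_detected = NA)
  }

  ev_nf <- build_events("neutropenic_fever", nf_ids, TRUE, 3L)
  ev_tr <- build_events("transfusion", tr_ids, TRUE, 2L)
  ev_mri <- build_events("mild_renal_impairment", mri_ids, TRUE, 2L)

  # CTCAE >= 3 tally: fever (grade 3) plus early AKI patients cover part of
  # it; the remainder is carried by grade-3 transfusions in patients with no
  # grade-3 event yet
  need <- con$ctcae3_count - length(unique(c(nf_ids,
                                             early_ids[early_type == "aki"])))
  cand <- sort(setdiff(tr_ids, nf_ids))
  if (need < 0 || need > length(cand)) {
    fail("CTCAE>=3 count unreachable from fever/transfusion assignment")
  }
  promote <- cand[seq_len(need)]
  ev_tr$ctcae_grade[ev_tr$patient_id %in% promote] <- 3L

  # germ detection among fever patients
  n_germ <- min(con$germ_detected_count %||% 0L, n_nf)
  ev_nf$germ_detected <- FALSE
  ev_nf$germ_detected[seq_len(n_germ)] <- TRUE

  ev_aki <- if (any(early_type == "aki")) {
    tibble(patient_id = early_ids[early_type == "aki"],
           event_type = "aki",
           onset_day = early_onset[early_type == "aki"],
           ctcae_grade = 3L, requires_hospitalization = TRUE,
           germ_detected = NA)
  } else empty_events()

  # nausea/diarrhea: not hospitalizing; split across SAE and non-SAE
  # patients so the any-AE tally is met
  n_na <- rates[["nausea_diarrhea"]]
  n_outside <- con$any_ae_count - con$any_sae_count
  if (n_outside < 0 || n_outside > n_na || n_sae + n_outside > n) {
    fail("any-AE count unreachable from nausea/diarrhea assignment")
  }
  na_ids <- c(ids[seq_len(n_na - n_outside)],
              ids[n_sae + seq_len(n_outside)])
  ms_na <- make_onset_multiset(n_na, summ$nausea_diarrhea$median,
                               summ$nausea_diarrhea$min,
                               summ$nausea_diarrhea$max)
  ev_na <- tibble(patient_id = sort(na_ids), event_type = "nausea_diarrhea",
                  onset_day = ms_na$rest, ctcae_grade = 2L,
                  requires_hospitalization = FALSE, germ_detected = NA)

  events <- bind_rows(ev_aki, ev_nf, ev_mri, ev_tr, ev_na) |>
    mutate(ctcae_grade = as.integer(.data$ctcae_grade),
           onset_day = as.integer(.data$onset_day),
           germ_detected = as.logical(.data$germ_detected)) |>
    arrange(.data$patient_id, .data$onset_day, .data$event_type)

  covs <- withr::with_seed(seed, {
    base <- draw_covariates(n, regimen, generator_params(n_patients = n))
    long <- draw_longitudinal(
      base, generator_params(n_patients = n),
      mri_flag = ids %in% mri_ids,
      nf_flag = ids %in% nf_ids,
      leuk_onset = leuk_onset)
    bind_cols(base, long)
  })

  patients <- tibble(
    patient_id = ids,
    admission_offset = as.integer(offsets),
    regimen = regimen,
    therapy_duration_days = as.integer(therapy_dur),
    leukopenia_onset_day = leuk_onset,
    leukopenia_duration_days = leuk_dur,
    scc_start_day = scc_start,
    scc_duration_days = scc_dur,
    scc_success = scc_success,
    post_scc_days = post_scc) |>
    bind_cols(covs)

  new_cohort(patients, events, provenance = "fixture",
             seed = as.integer(seed))
}

# -- verification -------------------------------------------------------------

summarise_onsets <- function(events, type) {
  x <- events$onset_day[events$event_type == type]
  if (length(x) == 0) return(c(median = NA_real_, min = NA_real_,
                               max = NA_real_))
  c(median = median(x), min = min(x), max = max(x))
}

#' Recount a cohort against a constraint set
#'
#' Recomputes every constrained summary from the cohort and compares it with
#' the expected value: size, regimen counts, admission bins, leukopenia and
#' collection summaries, per-event patient counts and onset
#' median/min/max, and the SAE tallies.
#'
#' @param cohort An `scm_cohort`.
#' @param constraints An `scm_constraints` list.
#' @return A tibble of class `scm_marginal_report` with columns `check`,
#'   `expected`, `observed`, `pass`; overall success is `all(report$pass)`
#'   (also stored in `attr(., "overall")`).
#' @export
verify_marginals <- function(cohort, constraints = default_constraints()) {
  con <- constraints
  p <- cohort$patients
  e <- cohort$events
  rows <- list()
  add <- function(check, expected, observed) {
    rows[[length(rows) + 1]] <<- tibble(
      check = check, expected = as.numeric(expected),
      observed = as.numeric(observed))
  }

  add("cohort_size", con$cohort_size, nrow(p))
  for (r in names(con$regimen_counts)) {
    add(paste0("regimen_", r), con$regimen_counts[[r]], sum(p$regimen == r))
  }
  gap <- -p$admission_offset
  add("admission_gap_0_1", con$admission_offset_bins[["0-1"]],
      sum(gap <= 1))
  add("admission_gap_2_4", con$admission_offset_bins[["2-4"]],
      sum(gap >= 2 & gap <= 4))

  has_leuk <- !is.na(p$leukopenia_onset_day)
  add("leukopenia_patients", con$leukopenia_count, sum(has_leuk))
  lo <- p$leukopenia_onset_day[has_leuk]
  add("leukopenia_onset_6_8", con$leukopenia_onset_bins[["6-8"]],
      sum(lo >= 6 & lo <= 8))
  add("leukopenia_onset_9plus", con$leukopenia_onset_bins[["9+"]],
      sum(lo >= 9))
  add("leukopenia_onset_median", con$leukopenia_onset_median, median(lo))
  ld <- p$leukopenia_duration_days[!is.na(p$leukopenia_duration_days)]
  add("leukopenia_duration_1_3", con$leukopenia_duration_bins[["1-3"]],
      sum(ld <= 3))
  add("leukopenia_duration_4_5", con$leukopenia_duration_bins[["4-5"]],
      sum(ld %in% 4:5))
  add("leukopenia_duration_6_8", con$leukopenia_duration_bins[["6-8"]],
      sum(ld >= 6 & ld <= 8))
  add("leukopenia_duration_median", con$leukopenia_duration_median,
      median(ld))

  si <- p$scc_start_day[p$scc_success]
  add("scc_success", con$scc_success_count, sum(p$scc_success))
  add("scc_interval_10_12", con$scc_interval_bins[["10-12"]],
      sum(si >= 10 & si <= 12))
  add("scc_interval_13_15", con$scc_interval_bins[["13-15"]],
      sum(si >= 13 & si <= 15))
  add("scc_interval_16_19", con$scc_interval_bins[["16-19"]],
      sum(si >= 16 & si <= 19))
  add("scc_interval_median", con$scc_interval_median, median(si))
  sd_ <- p$scc_duration_days[p$scc_success]
  for (d in names(con$scc_duration_counts)) {
    add(paste0("scc_duration_", d), con$scc_duration_counts[[d]],
        sum(sd_ == as.integer(d)))
  }

  for (t in names(con$event_rates)) {
    add(paste0("patients_", t), con$event_rates[[t]],
        n_distinct(e$patient_id[e$event_type == t]))
  }
  for (t in names(con$event_onset_summaries)) {
    s <- con$event_onset_summaries[[t]]
    obs <- summarise_onsets(e, t)
    add(paste0("onset_median_", t), s$median, obs[["median"]])
    add(paste0("onset_min_", t), s$min, obs[["min"]])
    add(paste0("onset_max_", t), s$max, obs[["max"]])
  }

  early <- is_early_sae(cohort)
  add("early_sae_patients", con$early_sae_count, sum(early$early_sae))
  sae_pat <- n_distinct(e$patient_id[e$requires_hospitalization])
  add("any_sae_patients", con$any_sae_count, sae_pat)
  g3_pat <- n_distinct(e$patient_id[!is.na(e$ctcae_grade) &
                                      e$ctcae_grade >= 3])
  add("ctcae3_patients", con$ctcae3_count, g3_pat)
  add("any_ae_patients", con$any_ae_count, n_distinct(e$patient_id))

  report <- bind_rows(rows) |>
    mutate(pass = !is.na(.data$observed) & .data$observed == .data$expected)
  attr(report, "overall") <- all(report$pass)
  class(report) <- c("scm_marginal_report", class(report))
  report
}
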