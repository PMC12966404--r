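# The bed-day simulator: maps each patient timeline through an admission
# policy to hospitalization intervals and aggregates occupied bed-days.
#
# Conventions (used consistently so normalized fractions are
# convention-invariant):
#   * closed integer day intervals; length = end - start + 1 (admission and
#     discharge days both occupy a bed);
#   * discharge day = max(SCC end + observed post-SCC days, therapy end,
#     leukopenia end, latest hospitalizing event onset);
#   * collection-failure patients keep their observed inpatient course in
#     every scenario.

#' Define an admission/treatment scenario
#'
#' A scenario couples a family with a sub-model. Families: `"current"`
#' (observed full inpatient course, the normalizing reference); `"day5"`
#' (patients without an early SAE are admitted on day 5 after therapy
#' start); `"empirical"` (admission at the observed first SAE);
#' `"worst"` / `"best"` (as empirical, but neutropenic fever shifted one day
#' earlier / later for febrile patients; rates unchanged). Sub-models:
#' `"X1"` therapy administered inpatient; `"X2"` therapy outpatient, SCC
#' inpatient regardless of SAEs (both X1/X2); `"X3"` therapy and SCC
#' outpatient unless an SAE has already led to admission before collection.
#' Early-SAE patients keep the observed full course in every family.
#'
#' @param family Scenario family (see above).
#' @param submodel `"X1"`, `"X2"` or `"X3"`; ignored for `"current"`.
#' @param outpatient_manageable Character vector of event types treated in
#'   an outpatient setting (their hospitalization flag is dropped before the
#'   policy is applied); default none.
#' @param label Display label; auto-generated when omitted.
#' @return A list of class `scm_scenario`.
#' @export
scenario_spec <- function(family = c("current", "day5", "worst", "empirical",
                                     "best"),
                          submodel = c("X1", "X2", "X3"),
                          outpatient_manageable = character(),
                          label = NULL) {
  family <- match.arg(family)
  submodel <- if (family == "current") NA_character_ else match.arg(submodel)
  stopifnot(all(outpatient_manageable %in% event_types()))
  if (family == "current" && length(outpatient_manageable) > 0) {
    abort("the current (observed) scenario admits no outpatient management")
  }
  nf_shift <- switch(family, worst = -1L, best = 1L, 0L)
  if (is.null(label)) {
    stem <- switch(family, current = "Current", day5 = "S5", worst = "SW",
                   empirical = "SE", best = "SB")
    label <- if (family == "current") stem else
      paste0(stem, substr(submodel, 2, 2))
    if (length(outpatient_manageable) > 0) {
      label <- paste0(label, "+out(",
                      paste(sort(outpatient_manageable), collapse = ","), ")")
    }
  }
  structure(list(family = family, submodel = submodel, nf_shift = nf_shift,
                 fixed_admission_day = if (family == "day5") 5L else NULL,
                 outpatient_manageable = outpatient_manageable,
                 label = label),
            class = "scm_scenario")
}

# per-patient discharge day from the observed (unshifted) timeline
discharge_days <- function(cohort) {
  p <- cohort$patients
  hosp <- filter(cohort$events, .data$requires_hospitalization)
  last_sae <- if (nrow(hosp) == 0) {
    tibble(patient_id = character(), last_sae = integer())
  } else {
    hosp |>
      group_by(.data$patient_id) |>
      summarise(last_sae = max(.data$onset_day), .groups = "drop")
  }
  p |>
    select("patient_id", "admission_offset", "therapy_duration_days",
           "leukopenia_onset_day", "leukopenia_duration_days",
           "scc_start_day", "scc_duration_days", "scc_success",
           "post_scc_days") |>
    left_join(last_sae, by = "patient_id") |>
    mutate(
      scc_end = if_else(.data$scc_success,
                        .data$scc_start_day + .data$scc_duration_days - 1L,
                        NA_integer_),
      leuk_end = .data$leukopenia_onset_day +
        coalesce(.data$leukopenia_duration_days, 1L) - 1L,
      discharge = pmax(
        if_else(.data$scc_success,
                .data$scc_end + coalesce(.data$post_scc_days, 0L),
                .data$therapy_duration_days - 1L),
        coalesce(.data$leuk_end, -4L),
        coalesce(.data$last_sae, -4L),
        0L)) |>
    select("patient_id", "scc_end", "discharge")
}

#' Apply a scenario's event modifications to a cohort
#'
#' Shifts every neutropenic-fever onset by the scenario's fever shift
#' (worst case -1 day, best case +1 day), clipped to day 0 below and to the
#' patient's discharge day above; drops the hospitalization flag of event
#' types the scenario manages in an outpatient setting. The rates of all
#' events — including kidney injury and transfusions — are unchanged.
#'
#' @param cohort An `scm_cohort`.
#' @param spec An `scm_scenario`.
#' @return A modified copy of the cohort.
#' @export
apply_scenario_events <- function(cohort, spec) {
  e <- cohort$events
  if (nrow(e) > 0 && spec$nf_shift != 0L) {
    disc <- discharge_days(cohort) |> select("patient_id", "discharge")
    e <- e |>
      left_join(disc, by = "patient_id") |>
      mutate(onset_day = if_else(
        .data$event_type == "neutropenic_fever",
        pmin(pmax(.data$onset_day + spec$nf_shift, 0L), .data$discharge),
        .data$onset_day)) |>
      select(-"discharge")
  }
  if (nrow(e) > 0 && length(spec$outpatient_manageable) > 0) {
    e <- e |>
      mutate(requires_hospitalization = .data$requires_hospitalization &
               !.data$event_type %in% spec$outpatient_manageable)
  }
  cohort$events <- e
  cohort
}

#' Hospitalization intervals under a scenario
#'
#' Applies the scenario policy to every patient and returns the merged,
#' closed integer day intervals during which a bed is occupied. Triggers:
#' `full_inpatient` (current family or failed collection), `early_sae`
#' (observed course kept for early-SAE patients), `sae` (admission at first
#' hospitalizing event), `day5_policy` (fixed day-5 admission),
#' `therapy_block` (X1), `scc_block` (inpatient collection). A patient
#' hospitalized at collection end stays the observed post-collection days;
#' otherwise the stay ends at collection end.
#'
#' @param cohort An `scm_cohort`.
#' @param spec An `scm_scenario`.
#' @return Tibble with `patient_id`, `start_day`, `end_day`, `trigger`;
#'   patients with no hospitalization contribute no rows.
#' @export
hospitalization_intervals <- function(cohort, spec) {
  disc <- discharge_days(cohort)
  early <- is_early_sae(cohort)
  shifted <- apply_scenario_events(cohort, spec)
  tsae <- first_sae_day(shifted)
  p <- cohort$patients |>
    select("patient_id", "admission_offset", "therapy_duration_days",
           "scc_start_day", "scc_success", "post_scc_days") |>
    left_join(disc, by = "patient_id") |>
    left_join(early, by = "patient_id") |>
    left_join(tsae, by = "patient_id")

  rows <- purrr::pmap(p, function(patient_id, admission_offset,
                                  therapy_duration_days, scc_start_day,
                                  scc_success, post_scc_days, scc_end,
                                  discharge, early_sae, first_sae_day) {
    full <- function(trigger) {
      tibble(patient_id = patient_id, start_day = admission_offset,
             end_day = discharge, trigger = trigger)
    }
    if (spec$family == "current") return(full("full_inpatient"))
    if (early_sae) return(full("early_sae"))
    if (!scc_success) return(full("full_inpatient"))

    starts <- integer(); ends <- integer(); trig <- character()
    add <- function(s, e, tr) {
      starts <<- c(starts, s); ends <<- c(ends, e); trig <<- c(trig, tr)
    }
    t_sae <- first_sae_day
    if (!is.na(t_sae)) add(t_sae, discharge, "sae")
    if (spec$family == "day5" && (is.na(t_sae) || t_sae > 5L)) {
      add(5L, discharge, "day5_policy")
    }
    if (identical(spec$submodel, "X1")) {
      add(0L, therapy_duration_days - 1L, "therapy_block")
    }
    scc_inpatient <- spec$submodel %in% c("X1", "X2") ||
      (identical(spec$submodel, "X3") && !is.na(t_sae) &&
         t_sae < scc_start_day)
    if (scc_inpatient) add(scc_start_day, scc_end, "scc_block")
    if (length(starts) == 0) return(NULL)

    iv <- merge_intervals(starts, ends, trig)
    # hospitalized at collection end => the observed post-collection days
    # are still needed
    covers <- iv$start_day <= scc_end & iv$end_day >= scc_end
    if (any(covers)) {
      iv$end_day[covers] <- pmax(iv$end_day[covers],
                                 scc_end + coalesce(post_scc_days, 0L))
      iv <- merge_intervals(iv$start_day, iv$end_day, iv$trigger)
    }
    iv$patient_id <- patient_id
    iv[, c("patient_id", "start_day", "end_day", "trigger")]
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(patient_id = character(), start_day = integer(),
                  end_day = integer(), trigger = character()))
  }
  out
}

merge_intervals <- function(starts, ends, triggers) {
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]; triggers <- triggers[o]
  ms <- starts[1]; me <- ends[1]; mt <- triggers[1]
  out_s <- integer(); out_e <- integer(); out_t <- character()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me + 1L) {  # adjacent days share one stay
      if (ends[i] > me) me <- ends[i]
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me); out_t <- c(out_t, mt)
      ms <- starts[i]; me <- ends[i]; mt <- triggers[i]
    }
  }
  tibble(start_day = c(out_s, ms), end_day = c(out_e, me),
         trigger = c(out_t, mt))
}

#' Total and component bed-days under a scenario
#'
#' Sums closed-interval lengths over all patients and splits them into the
#' pre-therapy component (days before day 0), therapy-to-collection
#' component, and post-collection component (days after collection end).
#'
#' @param cohort An `scm_cohort`.
#' @param spec An `scm_scenario`.
#' @param reference Optional `scm_bed_result` for the reference (observed)
#'   scenario; when supplied the normalized fraction is filled in.
#' @return An object of class `scm_bed_result`: total and component
#'   bed-days, per-patient bed-days, and (if available) the normalized
#'   fraction.
#' @export
bed_days <- function(cohort, spec = scenario_spec("current"),
                     reference = NULL) {
  iv <- hospitalization_intervals(cohort, spec)
  scc <- discharge_days(cohort) |> select("patient_id", "scc_end")
  per <- iv |>
    left_join(scc, by = "patient_id") |>
    mutate(
      len = .data$end_day - .data$start_day + 1L,
      pre = pmax(0L, pmin(.data$end_day, -1L) - .data$start_day + 1L),
      post = if_else(is.na(.data$scc_end), 0L,
                     pmax(0L, .data$end_day -
                            pmax(.data$start_day - 1L, .data$scc_end))),
      mid = .data$len - .data$pre - .data$post) |>
    group_by(.data$patient_id) |>
    summarise(bd = sum(.data$len), pre_therapy = sum(.data$pre),
              therapy_to_scc = sum(.data$mid), post_scc = sum(.data$post),
              .groups = "drop")
  per <- cohort$patients |>
    select("patient_id") |>
    left_join(per, by = "patient_id") |>
    mutate(across(c("bd", "pre_therapy", "therapy_to_scc", "post_scc"),
                  ~coalesce(.x, 0L)))
  res <- structure(
    list(label = spec$label, family = spec$family, submodel = spec$submodel,
         total_bd = sum(per$bd),
         component_bd = c(pre_therapy = sum(per$pre_therapy),
                          therapy_to_scc = sum(per$therapy_to_scc),
                          post_scc = sum(per$post_scc)),
         per_patient = per,
         normalized_fraction = NA_real_,
         ci_low = NA_real_, ci_high = NA_real_,
         n_boot = NA_integer_, seed = NA_integer_),
    class = "scm_bed_result")
  if (!is.null(reference)) res <- normalize_bed_days(res, reference)
  res
}

#' @export
print.scm_bed_result <- function(x, ...) {
  cat(sprintf("<scm_bed_result> %s: %d bed-days", x$label, x$total_bd))
  if (!is.na(x$normalized_fraction)) {
    cat(sprintf(" (%.3f of reference)", x$normalized_fraction))
  }
  cat("\n  components:",
      paste(names(x$component_bd), x$component_bd, sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Normalize a bed-day result against the observed course
#'
#' @param result,reference `scm_bed_result` objects (reference usually the
#'   `"current"` scenario).
#' @return `result` with `normalized_fraction` = total / reference total.
#' @export
normalize_bed_days <- function(result, reference) {
  if (reference$total_bd <= 0) {
    abort("reference scenario has zero bed-days; cannot normalize")
  }
  result$normalized_fraction <- result$total_bd / reference$total_bd
  result
}

#' Percentile bootstrap CI for the normalized bed-day fraction
#'
#' Resamples patients with replacement; each replicate recomputes the
#' scenario total and the reference total on the same resample and takes
#' their ratio. The 2.5 and 97.5 percentiles of the replicates form the
#' interval.
#'
#' @param cohort An `scm_cohort`.
#' @param spec An `scm_scenario`.
#' @param n_boot Number of bootstrap replicates (default 2000).
#' @param seed Integer seed.
#' @param reference_spec Reference scenario (default the observed course).
#' @return List with `ci_low`, `ci_high` and the point `fraction`.
#' @export
bootstrap_ci <- function(cohort, spec, n_boot = 2000, seed = 1,
                         reference_spec = scenario_spec("current")) {
  stopifnot(n_boot >= 2)
  bd_s <- bed_days(cohort, spec)$per_patient$bd
  bd_r <- bed_days(cohort, reference_spec)$per_patient$bd
  n <- length(bd_s)
  fracs <- withr::with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    tot_s <- matrix(bd_s[idx], nrow = n_boot)
    tot_r <- matrix(bd_r[idx], nrow = n_boot)
    rowSums(tot_s) / rowSums(tot_r)
  })
  ci <- unname(quantile(fracs, c(0.025, 0.975), na.rm = TRUE))
  list(ci_low = ci[1], ci_high = ci[2], fraction = sum(bd_s) / sum(bd_r))
}

#' Compare two scenarios' per-patient bed-day distributions
#'
#' Two-sided Wilcoxon/Mann-Whitney rank test on the per-patient bed-days
#' of the two scenarios (normal approximation; bed-days are heavily tied).
#'
#' @param cohort An `scm_cohort`.
#' @param spec_a,spec_b `scm_scenario` objects.
#' @return One-row tibble: labels, medians, rank statistic, p value.
#' @export
compare_scenarios <- function(cohort, spec_a, spec_b) {
  a <- bed_days(cohort, spec_a)$per_patient$bd
  b <- bed_days(cohort, spec_b)$per_patient$bd
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))
  tibble(label_a = spec_a$label, label_b = spec_b$label,
         median_a = median(a), median_b = median(b),
         statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Evaluate the full scenario grid
#'
#' Evaluates the observed course plus the named policy grid — day-5
#' admission (S51/S52), worst case (SW1/SW2), empirical (SE1/SE2/SE3) and
#' best case (SB1/SB2/SB3) — with normalized fractions and bootstrap CIs.
#' Optional supplementary variants additionally manage selected severe
#' events (renal impairment, transfusion, fever) in an outpatient setting.
#'
#' @param cohort An `scm_cohort`.
#' @param n_boot Bootstrap replicates per scenario (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @param include_supplementary Add the outpatient-management variants of
#'   SE3.
#' @return Tibble of class `scm_scenario_suite`: one row per scenario with
#'   totals, components, normalized fraction and CI.
#' @export
scenario_suite <- function(cohort, n_boot = 2000, seed = 1,
                           include_supplementary = FALSE) {
  specs <- list(scenario_spec("current"))
  grid <- list(day5 = c("X1", "X2"), worst = c("X1", "X2"),
               empirical = c("X1", "X2", "X3"), best = c("X1", "X2", "X3"))
  for (fam in names(grid)) {
    for (sub in grid[[fam]]) {
      specs[[length(specs) + 1]] <- scenario_spec(fam, sub)
    }
  }
  if (include_supplementary) {
    for (outp in list("mild_renal_impairment", "transfusion",
                      c("mild_renal_impairment", "transfusion"),
                      c("mild_renal_impairment", "transfusion",
                        "neutropenic_fever"))) {
      specs[[length(specs) + 1]] <-
        scenario_spec("empirical", "X3", outpatient_manageable = outp)
    }
  }
  ref <- bed_days(cohort, scenario_spec("current"))
  rows <- purrr::imap(specs, function(spec, i) {
    res <- bed_days(cohort, spec, reference = ref)
    ci <- bootstrap_ci(cohort, spec, n_boot = n_boot, seed = seed + i)
    tibble(label = res$label, family = res$family, submodel = res$submodel,
           total_bd = res$total_bd,
           pre_therapy_bd = res$component_bd[["pre_therapy"]],
           therapy_to_scc_bd = res$component_bd[["therapy_to_scc"]],
           post_scc_bd = res$component_bd[["post_scc"]],
           fraction = res$normalized_fraction,
           ci_low = ci$ci_low, ci_high = ci$ci_high)
  })
  out <- bind_rows(rows)
  class(out) <- c("scm_scenario_suite", class(out))
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  out
}
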