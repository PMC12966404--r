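# End-to-end driver and reporting figures.

#' Temporal profile of adverse events
#'
#' First occurrence per patient and event type as a day-resolved histogram
#' with a kernel density estimate (Gaussian kernel, Scott-type default
#' bandwidth), faceted by event type.
#'
#' @param cohort An `scm_cohort`.
#' @param bw Kernel bandwidth passed to [stats::density()] (default
#'   `"nrd"`, Scott's rule).
#' @return A ggplot object.
#' @export
plot_event_profile <- function(cohort, bw = "nrd") {
  if (nrow(cohort$events) == 0) {
    abort("cohort has no adverse events to plot")
  }
  firsts <- cohort$events |>
    group_by(.data$patient_id, .data$event_type) |>
    summarise(onset_day = min(.data$onset_day), .groups = "drop")
  ggplot2::ggplot(firsts, ggplot2::aes(x = .data$onset_day)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_density(ggplot2::aes(y = ggplot2::after_stat(count)),
                          bw = bw, colour = "firebrick",
                          linewidth = 0.7, na.rm = TRUE) +
    ggplot2::facet_wrap(~event_type, scales = "free_y") +
    ggplot2::labs(x = "day since therapy start",
                  y = "patients (first occurrence)",
                  title = "Temporal profile of adverse events") +
    ggplot2::theme_minimal()
}

#' Distribution of first severe-adverse-event onsets
#'
#' Stacked per-patient histogram of the first hospitalizing event day,
#' coloured by the triggering event type, with a kernel density estimate.
#' On cohorts following the study structure the plot shows the bimodal
#' split: early events on days 0--2, the remainder from day 5 onward, with
#' days 3--4 empty.
#'
#' @inheritParams plot_event_profile
#' @return A ggplot object.
#' @export
plot_sae_onset_distribution <- function(cohort, bw = "nrd") {
  sae <- cohort$events |>
    filter(.data$requires_hospitalization) |>
    group_by(.data$patient_id) |>
    slice_min(.data$onset_day, n = 1, with_ties = FALSE) |>
    ungroup()
  if (nrow(sae) == 0) abort("cohort has no severe adverse events to plot")
  ggplot2::ggplot(sae, ggplot2::aes(x = .data$onset_day,
                                    fill = .data$event_type)) +
    ggplot2::geom_histogram(binwidth = 1, colour = "grey30",
                            position = "stack") +
    ggplot2::geom_density(
      mapping = ggplot2::aes(x = .data$onset_day,
                             y = ggplot2::after_stat(count)),
      data = sae, inherit.aes = FALSE,
      bw = bw, colour = "black", linewidth = 0.7) +
    ggplot2::labs(x = "first SAE day since therapy start", y = "patients",
                  fill = "trigger",
                  title = "First severe adverse event onset") +
    ggplot2::theme_minimal()
}

#' Bar chart of scenario bed-day fractions
#'
#' Normalized bed-day fraction per scenario with bootstrap 95% error bars,
#' mirroring the scenario-comparison figure of the analysis.
#'
#' @param object An `scm_scenario_suite` from [scenario_suite()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scm_scenario_suite <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(label = factor(.data$label, levels = .data$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$fraction,
                                   fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "fraction of observed bed-days",
                  fill = "family",
                  title = "Simulated admission policies") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

write_stage <- function(df, path) {
  readr::write_csv(df, path)
  path
}

#' Run the full analysis pipeline
#'
#' Builds or accepts a cohort, verifies the published marginals (fixture
#' input only), evaluates the scenario grid with bootstrap CIs, runs the
#' two-step prediction reports, renders the figures, and writes every
#' artifact with an md5 manifest. Stages log via [message()]; any stage
#' failure aborts with the stage name.
#'
#' @param input The cohort source: an `scm_cohort`, an
#'   `scm_generator_params` (a synthetic cohort is drawn), or the string
#'   `"fixture"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed governing every stochastic stage.
#' @param n_boot Bootstrap replicates for the scenario suite.
#' @param include_supplementary Include outpatient-management scenario
#'   variants.
#' @param endpoints Endpoints for the classification report.
#' @param feature_set Feature set for the prediction reports.
#' @param cv_models Classifier registry names to evaluate.
#' @param figures Render PNG figures.
#' @return Tibble manifest (`stage`, `file`, `md5`), invisibly the list of
#'   results in `attr(., "results")`.
#' @export
run_pipeline <- function(input, out_dir, seed = 1, n_boot = 500,
                         include_supplementary = TRUE,
                         endpoints = "fever", feature_set = "clinical",
                         cv_models = c("logistic", "random_forest"),
                         figures = TRUE) {
  if (missing(input) || is.null(input)) {
    abort("no cohort source given: pass a cohort, generator parameters, or \"fixture\"",
          class = "scm_config_error")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    message(sprintf("[scmsim] stage: %s", name))
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  files <- list()
  results <- list()

  cohort <- stage("cohort", {
    if (inherits(input, "scm_cohort")) input
    else if (inherits(input, "scm_generator_params")) sample_cohort(input)
    else if (identical(input, "fixture")) build_fixture_cohort(seed = seed)
    else abort("unrecognised cohort source")
  })
  files$cohort <- file.path(out_dir, "cohort.json")
  write_cohort(cohort, files$cohort, format = "json")

  if (cohort$provenance == "fixture") {
    results$marginals <- stage("verify_marginals", {
      rep <- verify_marginals(cohort)
      if (!all(rep$pass)) abort("fixture cohort failed marginal checks")
      rep
    })
    files$marginals <- write_stage(results$marginals,
                                   file.path(out_dir, "marginal_report.csv"))
  }

  results$scenarios <- stage("scenario_suite", {
    scenario_suite(cohort, n_boot = n_boot, seed = seed,
                   include_supplementary = include_supplementary)
  })
  files$scenarios <- write_stage(results$scenarios,
                                 file.path(out_dir, "scenario_suite.csv"))

  results$classification <- stage("classification", {
    purrr::map(endpoints, function(ep) {
      ds <- make_ml_dataset(cohort, endpoint = ep,
                            feature_set = feature_set)
      glance(run_classification(ds, models = cv_models, seed = seed)) |>
        mutate(endpoint = ep)
    }) |> bind_rows()
  })
  files$classification <- write_stage(
    results$classification, file.path(out_dir, "classification_cv.csv"))

  results$onset <- stage("onset_regression", {
    ds <- make_ml_dataset(cohort, endpoint = "any_sae",
                          feature_set = feature_set)
    glance(run_onset_regression(ds, seed = seed))
  })
  files$onset <- write_stage(results$onset,
                             file.path(out_dir, "onset_cv.csv"))

  if (figures) {
    stage("figures", {
      ggplot2::ggsave(file.path(out_dir, "event_profile.png"),
                      plot_event_profile(cohort),
                      width = 8, height = 6, dpi = 150)
      ggplot2::ggsave(file.path(out_dir, "sae_onsets.png"),
                      plot_sae_onset_distribution(cohort),
                      width = 7, height = 4.5, dpi = 150)
      ggplot2::ggsave(file.path(out_dir, "scenario_fractions.png"),
                      autoplot(results$scenarios),
                      width = 8, height = 5, dpi = 150)
    })
    files$fig1 <- file.path(out_dir, "event_profile.png")
    files$fig2 <- file.path(out_dir, "sae_onsets.png")
    files$fig3 <- file.path(out_dir, "scenario_fractions.png")
  }

  manifest <- tibble(
    stage = names(files),
    file = unname(unlist(files)),
    md5 = unname(tools::md5sum(unlist(files))))
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  attr(manifest, "results") <- results
  manifest
}
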