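#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Per-fold classification scores
#'
#' @param x An `scm_cv` object from [run_classification()].
#' @param ... Unused.
#' @return Tibble with one row per (model, fold): accuracy, ROC-AUC, MCC.
#' @export
tidy.scm_cv <- function(x, ...) {
  x$fold_scores
}

#' Mean cross-validated classification scores
#'
#' @param x An `scm_cv` object.
#' @param ... Unused.
#' @return Tibble with one row per model: mean accuracy, ROC-AUC and MCC
#'   over the outer folds, plus endpoint, fold count and seed.
#' @export
glance.scm_cv <- function(x, ...) {
  x$fold_scores |>
    group_by(.data$model) |>
    summarise(accuracy = mean(.data$accuracy),
              roc_auc = mean(.data$roc_auc),
              mcc = mean(.data$mcc), .groups = "drop") |>
    mutate(endpoint = x$endpoint, n_folds = x$n_folds, seed = x$seed)
}

#' Per-fold onset-regression errors
#'
#' @param x An `scm_onset` object from [run_onset_regression()].
#' @param ... Unused.
#' @return Tibble with one row per (model, fold): MAD and RMSD in days.
#' @export
tidy.scm_onset <- function(x, ...) {
  x$fold_scores
}

#' Mean cross-validated onset-regression errors
#'
#' @param x An `scm_onset` object.
#' @param ... Unused.
#' @return Tibble with one row per model: mean MAD and RMSD in days.
#' @export
glance.scm_onset <- function(x, ...) {
  x$fold_scores |>
    group_by(.data$model) |>
    summarise(mad_days = mean(.data$mad_days),
              rmsd_days = mean(.data$rmsd_days), .groups = "drop") |>
    mutate(n_folds = x$n_folds, seed = x$seed)
}

#' One-row summary of a bed-day result
#'
#' @param x An `scm_bed_result` from [bed_days()].
#' @param ... Unused.
#' @return Tibble with the scenario label, total and component bed-days and
#'   the normalized fraction (if set).
#' @export
tidy.scm_bed_result <- function(x, ...) {
  tibble(label = x$label, family = x$family, submodel = x$submodel,
         total_bd = x$total_bd,
         pre_therapy_bd = x$component_bd[["pre_therapy"]],
         therapy_to_scc_bd = x$component_bd[["therapy_to_scc"]],
         post_scc_bd = x$component_bd[["post_scc"]],
         normalized_fraction = x$normalized_fraction)
}
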