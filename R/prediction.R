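# Two-step severe-adverse-event prediction: (1) classify whether a patient
# will develop an SAE after the 72 h window, (2) for predicted-positive
# patients regress the day of first SAE onset from admission-day features.

#' Estimated glomerular filtration rate (CKD-EPI 2021)
#'
#' Race-free CKD-EPI 2021 creatinine equation:
#' `142 * min(Scr/k, 1)^a * max(Scr/k, 1)^-1.200 * 0.9938^age * 1.012[female]`
#' with `k` = 0.7 (F) / 0.9 (M) and `a` = -0.241 (F) / -0.302 (M).
#'
#' @param creatinine_mg_dl Serum creatinine in mg/dL (> 0).
#' @param age_years Age in years.
#' @param sex `"M"` or `"F"` (vectorized).
#' @return eGFR in mL/min/1.73 m^2.
#' @export
egfr_ckdepi_2021 <- function(creatinine_mg_dl, age_years, sex) {
  if (any(creatinine_mg_dl <= 0, na.rm = TRUE)) {
    abort("creatinine must be positive", class = "scm_domain_error")
  }
  female <- sex == "F"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.241, -0.302)
  ratio <- creatinine_mg_dl / kappa
  142 * pmin(ratio, 1)^alpha * pmax(ratio, 1)^-1.200 *
    0.9938^age_years * ifelse(female, 1.012, 1)
}

#' Albumin-corrected calcium
#'
#' Conventional linear correction to an albumin reference of 4.0 g/dL:
#' 0.8 mg/dL (equivalently 0.2 mmol/L) of calcium per 1 g/dL of albumin
#' below reference.
#'
#' @param calcium Total serum calcium, in the unit named by `unit`.
#' @param albumin_g_dl Serum albumin in g/dL.
#' @param unit Unit of `calcium`: `"mg_dl"` (default) or `"mmol_l"`.
#' @return Corrected calcium in the same unit as the input.
#' @export
corrected_calcium <- function(calcium, albumin_g_dl,
                              unit = c("mg_dl", "mmol_l")) {
  unit <- match.arg(unit)
  per_g <- if (unit == "mg_dl") 0.8 else 0.2
  calcium + per_g * (4.0 - albumin_g_dl)
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0
#' when any marginal is empty.
#'
#' @param tp,fp,fn,tn Non-negative confusion-matrix counts.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(tp, fp, fn, tn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  num <- tp * tn - fp * fn
  ifelse(denom == 0, 0, num / denom)
}

#' Impute missing feature values
#'
#' Longitudinal lab values (admission / day 3 / day 5 triplets) are imputed
#' by the running average of that patient's available measurements of the
#' same lab; all remaining missing values by the column (population) mean.
#' Deterministic; no missing values remain afterwards.
#'
#' @param data Feature tibble as produced by [make_ml_dataset()] (id, label
#'   and onset columns are passed through untouched).
#' @return The tibble with all feature missingness resolved.
#' @export
impute_features <- function(data) {
  out <- data
  for (lab in lab_panel()) {
    cols <- c(lab, paste0("day3_", lab), paste0("day5_", lab))
    cols <- cols[cols %in% names(out)]
    if (length(cols) < 2) next
    series <- as.matrix(out[cols])
    run_avg <- rowMeans(series, na.rm = TRUE)
    for (col in cols) {
      miss <- is.na(out[[col]]) & is.finite(run_avg)
      out[[col]][miss] <- run_avg[miss]
    }
  }
  feat_cols <- setdiff(names(out), c("patient_id", "label", "onset_day"))
  for (col in feat_cols) {
    if (!is.numeric(out[[col]])) next
    miss <- is.na(out[[col]])
    if (all(miss)) {
      abort(sprintf("column '%s' has no observed values to impute from", col),
            class = "scm_imputation_error")
    }
    if (any(miss)) out[[col]][miss] <- mean(out[[col]], na.rm = TRUE)
  }
  out
}

#' Rank features by mutual information with a binary outcome
#'
#' Discrete plug-in estimator: continuous features are binned at sample
#' quantiles (`n_bins`), discrete features are used as-is; MI is computed in
#' nats against the label. Constant features get MI 0 and fall to the
#' bottom of the ranking.
#'
#' @param data Feature tibble including the label column.
#' @param label_col Name of the binary label column.
#' @param base_set Features always retained regardless of rank.
#' @param n_bins Number of quantile bins for continuous features.
#' @param top_k Number of top-ranked additions to mark as selected.
#' @return Tibble with `feature`, `mi`, `rank`, `in_base`, `selected`,
#'   ordered by decreasing MI.
#' @export
select_features_mi <- function(data, label_col = "label",
                               base_set = character(), n_bins = 4,
                               top_k = Inf) {
  y <- data[[label_col]]
  stopifnot(!is.null(y))
  feats <- setdiff(names(data), c("patient_id", label_col, "onset_day"))
  mi_one <- function(x) {
    if (is.numeric(x) && length(unique(x[!is.na(x)])) > n_bins) {
      brk <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                             na.rm = TRUE))
      if (length(brk) < 2) return(0)
      x <- cut(x, breaks = brk, include.lowest = TRUE)
    }
    tab <- table(x, y)
    if (nrow(tab) < 2) return(0)
    p <- tab / sum(tab)
    px <- rowSums(p); py <- colSums(p)
    terms <- p * log(p / outer(px, py))
    sum(terms[p > 0])
  }
  out <- tibble(feature = feats,
                mi = unname(vapply(feats, function(f) mi_one(data[[f]]),
                                   numeric(1)))) |>
    arrange(desc(.data$mi)) |>
    mutate(rank = row_number(),
           in_base = .data$feature %in% base_set,
           selected = .data$in_base | .data$rank <= top_k)
  out
}

# -- model registry -----------------------------------------------------------

# Each entry: a declared (frozen) hyperparameter grid, a fit(x, y, w, par)
# closure and a predict(model, x) closure. Additional entries with the same
# shape can be passed by the user (e.g. a tabular foundation-model wrapper)
# through the `models` argument of run_classification().
classifier_registry <- function() {
  list(
    logistic = list(
      grid = tibble(dummy = 1),
      fit = function(x, y, w, par) {
        suppressWarnings(stats::glm.fit(cbind(1, x), y, weights = w,
                                        family = stats::binomial()))
      },
      predict = function(m, x) {
        beta <- ifelse(is.na(m$coefficients), 0, m$coefficients)
        as.numeric(plogis(cbind(1, x) %*% beta))
      }),
    random_forest = list(
      grid = tibble(mtry_frac = c(0.33, 0.6)),
      fit = function(x, y, w, par) {
        ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                       probability = TRUE, num.trees = 300,
                       mtry = max(1, floor(par$mtry_frac * ncol(x))),
                       case.weights = w, seed = 7, num.threads = 1)
      },
      predict = function(m, x) {
        stats::predict(m, data = as.data.frame(x),
                       num.threads = 1)$predictions[, "1"]
      }),
    gradient_boosting = list(
      grid = tidyr::expand_grid(nrounds = c(50, 150), max_depth = c(2, 3)),
      fit = function(x, y, w, par) {
        spw <- sum(y == 0) / max(1, sum(y == 1))
        xgboost::xgb.train(
          params = list(objective = "binary:logistic",
                        max_depth = par$max_depth, eta = 0.1,
                        scale_pos_weight = spw, nthread = 1),
          data = xgboost::xgb.DMatrix(x, label = y),
          nrounds = par$nrounds, verbose = 0)
      },
      predict = function(m, x) {
        stats::predict(m, xgboost::xgb.DMatrix(x))
      }))
}

regressor_registry <- function() {
  list(
    elastic_net = list(
      fit = function(x, y) {
        if (stats::var(y) == 0 || ncol(x) < 2) {
          structure(list(mean = mean(y)), class = "scm_mean_predictor")
        } else {
          cv <- glmnet::cv.glmnet(x, y, alpha = 0.5,
                                  nfolds = min(5, length(y)))
          structure(list(fit = cv), class = "scm_glmnet")
        }
      },
      predict = function(m, x) {
        if (inherits(m, "scm_mean_predictor")) rep(m$mean, nrow(x))
        else as.numeric(stats::predict(m$fit, newx = x, s = "lambda.min"))
      }),
    random_forest = list(
      fit = function(x, y) {
        ranger::ranger(x = x, y = y, num.trees = 300, seed = 7,
                       num.threads = 1)
      },
      predict = function(m, x) {
        stats::predict(m, data = as.data.frame(x),
                       num.threads = 1)$predictions
      }),
    gradient_boosting = list(
      fit = function(x, y) {
        xgboost::xgb.train(
          params = list(objective = "reg:squarederror",
                        max_depth = 2, eta = 0.1, nthread = 1),
          data = xgboost::xgb.DMatrix(x, label = y),
          nrounds = 100, verbose = 0)
      },
      predict = function(m, x) {
        stats::predict(m, xgboost::xgb.DMatrix(x))
      }))
}

feature_matrix <- function(data) {
  feat_cols <- setdiff(names(data), c("patient_id", "label", "onset_day"))
  x <- as.matrix(data[feat_cols])
  storage.mode(x) <- "double"
  x
}

stratified_folds <- function(y, k) {
  if (min(table(y)) < k) {
    abort(paste("a fold would lack one of the classes;",
                "reduce the number of folds"),
          class = "scm_stratification_error")
  }
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

class_weights <- function(y) {
  tab <- table(factor(y, levels = c(0, 1)))
  n <- length(y)
  w <- n / (2 * as.numeric(tab[as.character(y)]))
  w
}

fold_auc <- function(y, prob) {
  if (length(unique(y)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = prob,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

fold_metrics <- function(y, prob, threshold) {
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1); tn <- sum(pred == 0 & y == 0)
  tibble(accuracy = mean(pred == y),
         roc_auc = fold_auc(y, prob),
         mcc = mcc(tp, fp, fn, tn))
}

resolve_models <- function(models, registry) {
  if (is.character(models)) {
    unknown <- setdiff(models, names(registry))
    if (length(unknown) > 0) {
      abort(sprintf("unknown model(s): %s", paste(unknown, collapse = ", ")))
    }
    registry[models]
  } else {
    models  # user-supplied registry entries (pluggable classifiers)
  }
}

#' Cross-validated SAE occurrence classification
#'
#' Stratified k-fold cross-validation with class-weighted fitting.
#' Hyperparameters are selected per outer fold by an inner stratified CV
#' over each model's declared (frozen) grid — a nested CV, so the outer
#' scores are selection-unbiased. Reports per-fold and mean accuracy,
#' ROC-AUC and MCC; fold metrics are averaged, not pooled.
#'
#' @param data Dataset from [make_ml_dataset()] (columns `patient_id`,
#'   `label`, `onset_day`, features). Missing features are imputed first.
#' @param models Character vector of registry models (`"logistic"`,
#'   `"random_forest"`, `"gradient_boosting"`) or a named list of custom
#'   entries with `grid`/`fit`/`predict` (e.g. a tabular foundation-model
#'   plug-in).
#' @param n_folds Outer folds (default 5).
#' @param inner_folds Inner folds for hyperparameter selection (default 3).
#' @param seed Integer seed; results are reproducible bit-for-bit.
#' @param threshold Probability cut for accuracy/MCC (default 0.5).
#' @return An `scm_cv` object; see [tidy.scm_cv()] and [glance.scm_cv()].
#' @export
run_classification <- function(data, models = c("logistic", "random_forest",
                                                "gradient_boosting"),
                               n_folds = 5, inner_folds = 3, seed = 1,
                               threshold = 0.5) {
  entries <- resolve_models(models, classifier_registry())
  data <- impute_features(data)
  y <- data$label
  if (length(unique(y)) < 2) {
    abort("classification needs both classes present")
  }
  x <- feature_matrix(data)

  scores <- withr::with_seed(seed, {
    fold <- stratified_folds(y, n_folds)
    purrr::imap(entries, function(entry, name) {
      purrr::map(seq_len(n_folds), function(f) {
        tr <- fold != f
        par <- select_hyperparameters(entry, x[tr, , drop = FALSE], y[tr],
                                      inner_folds, threshold)
        m <- entry$fit(x[tr, , drop = FALSE], y[tr],
                       class_weights(y[tr]), par)
        prob <- entry$predict(m, x[!tr, , drop = FALSE])
        fold_metrics(y[!tr], prob, threshold) |>
          mutate(model = name, fold = f, .before = 1)
      }) |> bind_rows()
    }) |> bind_rows()
  })
  structure(list(fold_scores = scores,
                 endpoint = attr(data, "endpoint") %||% NA_character_,
                 n_folds = n_folds, seed = seed, threshold = threshold),
            class = "scm_cv")
}

select_hyperparameters <- function(entry, x, y, inner_folds, threshold) {
  grid <- entry$grid %||% tibble(dummy = 1)
  if (nrow(grid) <= 1) return(as.list(grid[1, , drop = FALSE]))
  k <- min(inner_folds, min(table(y)))
  if (k < 2) return(as.list(grid[1, , drop = FALSE]))
  fold <- stratified_folds(y, k)
  aucs <- vapply(seq_len(nrow(grid)), function(g) {
    par <- as.list(grid[g, , drop = FALSE])
    mean(vapply(seq_len(k), function(f) {
      tr <- fold != f
      m <- entry$fit(x[tr, , drop = FALSE], y[tr], class_weights(y[tr]), par)
      fold_auc(y[!tr], entry$predict(m, x[!tr, , drop = FALSE]))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  as.list(grid[which.max(aucs), , drop = FALSE])
}

#' Cross-validated SAE onset regression
#'
#' For patients who develop a qualifying SAE, regresses the day of first
#' onset on admission-day features only (day-3/day-5 columns are dropped)
#' in k-fold cross-validation, reporting the mean absolute deviation (MAD)
#' and root-mean-squared deviation (RMSD) in days, averaged over folds.
#'
#' @param data Dataset from [make_ml_dataset()].
#' @param models Registry models: `"elastic_net"`, `"random_forest"`,
#'   `"gradient_boosting"`, or a named list of custom entries.
#' @param n_folds Folds (default 3).
#' @param seed Integer seed.
#' @return An `scm_onset` object; see [tidy.scm_onset()] /
#'   [glance.scm_onset()].
#' @export
run_onset_regression <- function(data, models = c("elastic_net",
                                                  "random_forest",
                                                  "gradient_boosting"),
                                 n_folds = 3, seed = 1) {
  entries <- resolve_models(models, regressor_registry())
  pos <- data |> filter(.data$label == 1, !is.na(.data$onset_day))
  if (nrow(pos) < n_folds) {
    abort(sprintf(
      "only %d patients with an SAE onset; at least %d needed for %d folds",
      nrow(pos), n_folds, n_folds))
  }
  pos <- impute_features(pos)
  admission_cols <- !grepl("^day[35]_", names(pos))
  pos <- pos[admission_cols]
  y <- as.numeric(pos$onset_day)
  x <- feature_matrix(pos)

  scores <- withr::with_seed(seed, {
    fold <- rep_len(seq_len(n_folds), length(y))[sample.int(length(y))]
    purrr::imap(entries, function(entry, name) {
      purrr::map(seq_len(n_folds), function(f) {
        tr <- fold != f
        m <- entry$fit(x[tr, , drop = FALSE], y[tr])
        pred <- entry$predict(m, x[!tr, , drop = FALSE])
        err <- pred - y[!tr]
        tibble(model = name, fold = f,
               mad_days = mean(abs(err)),
               rmsd_days = sqrt(mean(err^2)))
      }) |> bind_rows()
    }) |> bind_rows()
  })
  structure(list(fold_scores = scores, n_folds = n_folds, seed = seed),
            class = "scm_onset")
}

# -- two-step framework -------------------------------------------------------

#' Fit a single SAE occurrence classifier on a full dataset
#'
#' @param data Dataset from [make_ml_dataset()].
#' @param model Registry model name (default `"logistic"`).
#' @param seed Integer seed.
#' @param inner_folds Folds used to pick the hyperparameters.
#' @return An `scm_classifier` usable with [two_step_predict()].
#' @export
fit_sae_classifier <- function(data, model = "logistic", seed = 1,
                               inner_folds = 3) {
  entry <- resolve_models(model, classifier_registry())[[1]]
  data <- impute_features(data)
  x <- feature_matrix(data)
  y <- data$label
  fit <- withr::with_seed(seed, {
    par <- select_hyperparameters(entry, x, y, inner_folds, 0.5)
    entry$fit(x, y, class_weights(y), par)
  })
  structure(list(entry = entry, fit = fit, features = colnames(x),
                 model = if (is.character(model)) model else names(model)),
            class = "scm_classifier")
}

#' Fit a single SAE onset regressor on the positive patients
#'
#' Admission-day features only.
#'
#' @inheritParams fit_sae_classifier
#' @param model Regressor registry name (default `"elastic_net"`).
#' @return An `scm_regressor` usable with [two_step_predict()].
#' @export
fit_onset_regressor <- function(data, model = "elastic_net", seed = 1) {
  entry <- resolve_models(model, regressor_registry())[[1]]
  pos <- data |> filter(.data$label == 1, !is.na(.data$onset_day))
  pos <- impute_features(pos)
  pos <- pos[!grepl("^day[35]_", names(pos))]
  x <- feature_matrix(pos)
  fit <- withr::with_seed(seed, entry$fit(x, as.numeric(pos$onset_day)))
  structure(list(entry = entry, fit = fit, features = colnames(x)),
            class = "scm_regressor")
}

align_features <- function(newdata, features) {
  missing_cols <- setdiff(features, names(newdata))
  if (length(missing_cols) > 0) {
    abort(sprintf("new data lacks feature column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "scm_schema_error")
  }
  x <- as.matrix(newdata[features])
  storage.mode(x) <- "double"
  x
}

#' Two-step prediction: occurrence, then onset
#'
#' Applies the first-stage classifier to every patient; patients whose SAE
#' probability reaches the decision threshold additionally receive a
#' predicted onset day from the second-stage regressor, supporting
#' admission planning. The threshold is exposed so the first stage can be
#' tuned to the cost of misclassification.
#'
#' @param classifier An `scm_classifier`.
#' @param regressor An `scm_regressor`.
#' @param new_data Feature tibble (same columns as the training dataset).
#' @param threshold Classifier decision threshold (default 0.5).
#' @return Tibble with `patient_id` (when present), `sae_probability` and
#'   `predicted_onset_day` (`NA` below threshold).
#' @export
two_step_predict <- function(classifier, regressor, new_data,
                             threshold = 0.5) {
  new_data <- impute_features(new_data)
  xc <- align_features(new_data, classifier$features)
  prob <- classifier$entry$predict(classifier$fit, xc)
  onset <- rep(NA_real_, nrow(new_data))
  sel <- prob >= threshold
  if (any(sel)) {
    xr <- align_features(new_data[sel, , drop = FALSE], regressor$features)
    onset[sel] <- regressor$entry$predict(regressor$fit, xr)
  }
  out <- tibble(sae_probability = prob, predicted_onset_day = onset)
  if ("patient_id" %in% names(new_data)) {
    out <- bind_cols(tibble(patient_id = new_data$patient_id), out)
  }
  out
}
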