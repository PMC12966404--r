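test_that("CKD-EPI 2021 eGFR matches the published equation", {
  # at the creatinine breakpoint both power terms are 1
  expect_equal(egfr_ckdepi_2021(0.7, 50, "F"),
               142 * 0.9938^50 * 1.012)
  expect_equal(egfr_ckdepi_2021(0.9, 60, "M"), 142 * 0.9938^60)
  # independent hand calculation for a standard case
  expect_equal(egfr_ckdepi_2021(1.0, 60, "M"),
               142 * (1.0 / 0.9)^-1.200 * 0.9938^60)
  # monotone decreasing in creatinine
  cr <- seq(0.4, 4, by = 0.2)
  expect_true(all(diff(egfr_ckdepi_2021(cr, 60, "M")) < 0))
  expect_true(all(diff(egfr_ckdepi_2021(cr, 60, "F")) < 0))
  expect_error(egfr_ckdepi_2021(0, 60, "M"), class = "scm_domain_error")
})

test_that("corrected calcium applies the conventional albumin rule", {
  expect_equal(corrected_calcium(9.4, 4.0), 9.4)
  expect_equal(corrected_calcium(9.0, 3.0), 9.8)
  expect_equal(corrected_calcium(2.2, 3.0, unit = "mmol_l"), 2.4)
  alb <- seq(2, 5, 0.5)
  expect_equal(diff(corrected_calcium(9, alb)), rep(-0.4, 6))  # linear
})

test_that("MCC equals the point correlation of prediction and truth", {
  expect_equal(mcc(5, 0, 0, 5), 1)
  expect_equal(mcc(0, 5, 5, 0), -1)
  expect_equal(mcc(3, 1, 2, 4), -mcc(2, 4, 3, 1))  # label swap antisymmetry
  expect_equal(mcc(5, 5, 0, 0), 0)                 # empty marginal
  withr::with_seed(99, {
    for (i in 1:1000) {
      cnt <- rmultinom(1, size = sample(4:60, 1), prob = runif(4))[, 1]
      tp <- cnt[1]; fp <- cnt[2]; fn <- cnt[3]; tn <- cnt[4]
      pred <- rep(c(1, 1, 0, 0), times = c(tp, fp, fn, tn))
      truth <- rep(c(1, 0, 1, 0), times = c(tp, fp, fn, tn))
      oracle <- suppressWarnings(stats::cor(pred, truth))
      if (is.na(oracle)) oracle <- 0
      expect_equal(mcc(tp, fp, fn, tn), oracle, tolerance = 1e-12)
    }
  })
})

test_that("imputation uses running averages then population means", {
  ds <- dplyr::bind_rows(purrr::map(1:4, function(i) {
    toy_patient(sprintf("I%02d", i))
  })) |>
    dplyr::mutate(label = 0L, onset_day = NA_integer_) |>
    dplyr::select(patient_id, label, onset_day, hemoglobin_g_dl,
                  day3_hemoglobin_g_dl, day5_hemoglobin_g_dl, ldh_u_l)
  expect_equal(impute_features(ds), ds)  # nothing missing: identity

  ds$hemoglobin_g_dl[1] <- 10; ds$day5_hemoglobin_g_dl[1] <- 8
  ds$day3_hemoglobin_g_dl[1] <- NA
  ds$ldh_u_l <- c(NA, 200, 300, 250)
  out <- impute_features(ds)
  expect_equal(out$day3_hemoglobin_g_dl[1], 9)   # mean of own series
  expect_equal(out$ldh_u_l[1], 250)              # column mean
  feat <- dplyr::select(out, -patient_id, -label, -onset_day)
  expect_false(anyNA(feat))

  ds$ldh_u_l <- NA_real_
  expect_error(impute_features(ds), "ldh_u_l",
               class = "scm_imputation_error")
})

test_that("mutual-information ranking finds planted signal", {
  withr::with_seed(5, {
    n <- 2000
    y <- rbinom(n, 1, 0.4)
    ds <- tibble::tibble(
      label = y,
      signal = y + rnorm(n, sd = 0.6),
      copy = y,                     # identical to the label
      noise1 = rnorm(n), noise2 = rnorm(n), noise3 = runif(n))
  })
  mi <- select_features_mi(ds)
  expect_lt(mi$mi[mi$feature == "noise1"], 0.01)
  py <- mean(ds$label)
  entropy <- -py * log(py) - (1 - py) * log(1 - py)
  expect_equal(mi$mi[mi$feature == "copy"], entropy, tolerance = 1e-10)
  expect_true(all(c("copy", "signal") %in% mi$feature[1:3]))
  # constant features fall to the bottom with zero information
  ds$flat <- 1
  mi2 <- select_features_mi(ds)
  expect_equal(mi2$mi[mi2$feature == "flat"], 0)
})

test_that("classification is perfect on separable data and reproducible", {
  withr::with_seed(11, {
    n <- 120
    y <- rep(0:1, each = n / 2)
    ds <- tibble::tibble(patient_id = as.character(seq_len(n)),
                         label = y, onset_day = NA_integer_,
                         x1 = y * 10 + rnorm(n, sd = 0.1),
                         x2 = rnorm(n))
  })
  cv <- run_classification(ds, models = "logistic", seed = 1)
  g <- glance(cv)
  expect_equal(g$accuracy, 1)
  expect_equal(g$roc_auc, 1)
  expect_equal(g$mcc, 1)
  cv2 <- run_classification(ds, models = "logistic", seed = 1)
  expect_equal(tidy(cv2), tidy(cv))  # bit-for-bit reproducible
})

test_that("no leakage: permuted labels score at chance", {
  aucs <- purrr::map_dbl(1:8, function(s) {
    withr::with_seed(100 + s, {
      co <- sample_cohort(generator_params(n_patients = 250, seed = 200 + s))
      ds <- make_ml_dataset(co, "fever", "clinical")
      ds$label <- sample(ds$label)
    })
    glance(run_classification(ds, models = "logistic", seed = s))$roc_auc
  })
  se <- stats::sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 0.02)
})

test_that("a planted signal is detected above AUC 0.7 at n = 500", {
  eff <- planted_effect("hemoglobin_g_dl", "neutropenic_fever", 1.5)
  co <- sample_cohort(generator_params(n_patients = 500, seed = 17,
                                       effect_spec = eff,
                                       missingness_rate = 0))
  ds <- make_ml_dataset(co, "fever", "clinical")
  g <- glance(run_classification(ds, models = "logistic", seed = 1))
  expect_gt(g$roc_auc, 0.7)
})

test_that("stratification refuses folds that would lack a class", {
  ds <- tibble::tibble(patient_id = as.character(1:20),
                       label = c(rep(0L, 17), rep(1L, 3)),
                       onset_day = NA_integer_, x = rnorm(20))
  expect_error(run_classification(ds, models = "logistic", n_folds = 5),
               "folds", class = "scm_stratification_error")
})

test_that("onset regression attains the analytic noise floor", {
  # constant onset: every model should be exact
  dsc <- tibble::tibble(patient_id = as.character(1:30), label = 1L,
                        onset_day = 9, x1 = rnorm(30), x2 = rnorm(30))
  g0 <- glance(run_onset_regression(dsc, models = "elastic_net", seed = 1))
  expect_equal(g0$mad_days, 0, tolerance = 1e-8)
  expect_equal(g0$rmsd_days, 0, tolerance = 1e-8)

  # linear onset in creatinine with unit Gaussian noise: MAD floor is
  # E|N(0,1)| = sqrt(2/pi) ~ 0.80 days
  withr::with_seed(21, {
    n <- 150
    cr <- rnorm(n, 1, 0.3)
    ds <- tibble::tibble(patient_id = as.character(seq_len(n)), label = 1L,
                         onset_day = 7 + 3 * (cr - 1) + rnorm(n),
                         creatinine_mg_dl = cr, other = rnorm(n))
  })
  g <- glance(run_onset_regression(ds, models = "elastic_net", seed = 2))
  expect_lt(abs(g$mad_days - sqrt(2 / pi)), 0.2)
  # RMSD >= MAD on every fold of every model
  rep_all <- run_onset_regression(ds, seed = 3)
  expect_true(all(tidy(rep_all)$rmsd_days >= tidy(rep_all)$mad_days))
  few <- dsc[1:2, ]
  expect_error(run_onset_regression(few, n_folds = 3), "at least")
})

test_that("two-step prediction gates the onset on the classifier", {
  withr::with_seed(31, {
    n <- 160
    y <- rep(0:1, each = n / 2)
    ds <- tibble::tibble(patient_id = as.character(seq_len(n)), label = y,
                         onset_day = ifelse(y == 1, 8 + rbinom(n, 4, 0.5),
                                            NA_real_),
                         x1 = y * 6 + rnorm(n), x2 = rnorm(n))
  })
  clf <- fit_sae_classifier(ds, "logistic", seed = 1)
  reg <- fit_onset_regressor(ds, "elastic_net", seed = 1)
  pred <- two_step_predict(clf, reg, ds, threshold = 0.5)
  expect_true(all(is.na(pred$predicted_onset_day[pred$sae_probability < 0.5])))
  expect_true(all(!is.na(pred$predicted_onset_day[
    pred$sae_probability >= 0.5])))
  # degenerate threshold: everyone receives an onset estimate
  pred0 <- two_step_predict(clf, reg, ds, threshold = 0)
  expect_false(anyNA(pred0$predicted_onset_day))
  expect_error(two_step_predict(clf, reg, dplyr::select(ds, -x1)),
               "x1", class = "scm_schema_error")
})
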