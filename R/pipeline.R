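#' Prepare a raw tabular dataset for survival modelling
#'
#' Registry-style cleaning: feature columns whose missing fraction exceeds
#' \code{missing_threshold} are dropped unless explicitly kept (a clinically
#' important variable can be retained despite heavy missingness); remaining
#' numeric features are mean-imputed and categorical features mode-imputed;
#' categoricals are then one-hot encoded. Every dropped or imputed column is
#' reported via messages.
#'
#' @param raw data frame with columns \code{id}, \code{time}, \code{event}
#'   and arbitrary feature columns.
#' @param missing_threshold drop features missing more than this fraction
#'   (default 0.8).
#' @param keep_list feature names exempt from the missingness rule.
#' @param verbose emit a message per dropped/imputed column (default TRUE).
#' @return A \code{\link{as_survival_data}} object with numeric features
#'   only.
#' @export
prepare_survival_data <- function(raw, missing_threshold = 0.8,
                                  keep_list = character(), verbose = TRUE) {
  raw <- as.data.frame(raw)
  need <- c("id", "time", "event")
  if (!all(need %in% names(raw))) {
    stop("missing mandatory column(s): ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  }
  feats <- setdiff(names(raw), need)
  say <- function(...) if (verbose) message(sprintf(...))
  out <- raw[need]
  for (f in feats) {
    col <- raw[[f]]
    miss <- mean(is.na(col) | (is.character(col) & col == ""))
    if (miss > missing_threshold && !(f %in% keep_list)) {
      say("prepare: dropped '%s' (%.0f%% missing)", f, 100 * miss)
      next
    }
    if (is.numeric(col)) {
      if (anyNA(col)) {
        col[is.na(col)] <- mean(col, na.rm = TRUE)
        say("prepare: mean-imputed '%s'", f)
      }
      out[[f]] <- col
    } else {
      col <- as.character(col)
      col[col == ""] <- NA_character_
      if (anyNA(col)) {
        tab <- table(col)
        col[is.na(col)] <- names(tab)[which.max(tab)]
        say("prepare: mode-imputed '%s'", f)
      }
      lev <- sort(unique(col))
      # one-hot encode; drop the first level as reference when binary
      keep_lev <- if (length(lev) == 2L) lev[-1L] else lev
      for (lv in keep_lev) {
        out[[paste0(f, "_", make.names(lv))]] <- as.numeric(col == lv)
      }
      say("prepare: one-hot encoded '%s' (%d levels)", f, length(lev))
    }
  }
  as_survival_data(out)
}

#' Run the full survival-estimation pipeline
#'
#' Orchestrates the stages end to end on a training/test split of the data:
#' augmentation, classifier fitting, ABBQ calibration (fitted on a held-out
#' calibration slice of the training scores, never on test data), individual
#' curve prediction, survival-time estimation (threshold, gradient,
#' regression), and curve metrics. Deterministic for a fixed seed and
#' classifier family.
#'
#' @param data a \code{\link{as_survival_data}} object.
#' @param horizon study horizon \code{P}.
#' @param family classifier family, see \code{\link{case_classifier}}.
#' @param bin_candidates ABBQ bin counts to tune over; a single value skips
#'   tuning.
#' @param theta threshold for the threshold estimator.
#' @param window window (periods) for windowed accuracy.
#' @param test_fraction fraction of subjects held out as the test set.
#' @param calib_fraction fraction of the training subjects held out for
#'   calibration fitting and bin-count tuning.
#' @param seed master seed for the split, fitting and calibration.
#' @param compute_importance also compute \code{\link{temporal_importance}}
#'   on the training survivors (xgboost family only).
#' @param grid_step quadrature step for the curve metrics.
#' @return A list of class \code{"case_run"}: the fitted \code{model},
#'   \code{calibration} map, test-set \code{curves}, survival-time
#'   \code{estimates} (per method), \code{metrics} (ECE before/after
#'   calibration, mAUSC, windowed accuracies, class ratio), the
#'   \code{split} (subject ids), and optionally \code{importance}.
#' @export
run_case_pipeline <- function(data, horizon, family = "xgboost",
                              bin_candidates = c(5L, 10L, 20L, 50L),
                              theta = 0.5, window = 5,
                              test_fraction = 0.25, calib_fraction = 0.25,
                              seed = 1L, compute_importance = FALSE,
                              grid_step = 0.01) {
  stopifnot(inherits(data, "survival_data"))
  horizon <- check_horizon(horizon)
  n <- nrow(data)
  set.seed(seed)
  test_ids <- sort(sample.int(n, max(1L, round(test_fraction * n))))
  train <- subset_survival(data, setdiff(seq_len(n), test_ids))
  test <- subset_survival(data, test_ids)
  n_tr <- nrow(train)
  calib_ids <- sort(sample.int(n_tr, max(1L, round(calib_fraction * n_tr))))
  fit_part <- subset_survival(train, setdiff(seq_len(n_tr), calib_ids))
  calib_part <- subset_survival(train, calib_ids)

  aug_fit <- case_augment(fit_part, horizon)
  model <- fit_classifier(case_classifier(family), aug_fit, seed = seed)

  aug_cal <- case_augment(calib_part, horizon)
  raw_cal <- score_classifier(model, aug_cal)
  half <- seq_len(floor(length(raw_cal) / 2))
  tuned <- tune_bin_count(raw_cal[half], aug_cal$label[half],
                          raw_cal[-half], aug_cal$label[-half],
                          candidates = bin_candidates)
  map <- fit_abbq(raw_cal, aug_cal$label, bins = tuned$best)

  curves_test <- predict_curves(model, map, test, horizon)
  curves_train <- predict_curves(model, map, train, horizon)

  d_surv_train <- attach_survival_features(train, curves_train)
  d_surv_test <- attach_survival_features(test, curves_test)
  regressor <- fit_time_regressor(d_surv_train, train, seed = seed)

  est <- list(threshold = estimate_time_threshold(curves_test, theta = theta),
              gradient = estimate_time_gradient(curves_test),
              regression = predict(regressor, d_surv_test))

  ev <- test$event == 1
  acc <- if (any(ev)) {
    vapply(est, function(e) {
      windowed_accuracy(e[test$id[ev]], test$time[ev], window = window)
    }, numeric(1))
  } else c(threshold = NA_real_, gradient = NA_real_, regression = NA_real_)

  aug_test <- case_augment(test, horizon)
  raw_test <- score_classifier(model, aug_test)
  ece_raw <- ece(raw_test, aug_test$label)
  ece_cal <- ece(predict(map, raw_test), aug_test$label)

  m_case <- if (any(ev)) mausc(curves_test, test, grid_step = grid_step) else NA
  km <- km_baseline(train)
  m_km <- if (any(ev)) {
    mausc(km_curve_matrix(km, horizon, test$id), test, grid_step = grid_step)
  } else NA

  out <- list(model = model, calibration = map, bins = tuned$best,
              curves = curves_test, regressor = regressor, estimates = est,
              km = km,
              metrics = list(class_ratio = case_class_ratio(data, horizon),
                             ece_uncalibrated = ece_raw,
                             ece_calibrated = ece_cal,
                             mausc_case = as.numeric(m_case),
                             mausc_km = as.numeric(m_km),
                             windowed_accuracy = acc),
              split = list(train = train$id, test = test$id),
              horizon = horizon, seed = seed)
  if (compute_importance && family == "xgboost") {
    out$importance <- temporal_importance(model, train, horizon, seed = seed)
  }
  structure(out, class = "case_run")
}

subset_survival <- function(data, idx) {
  structure(as.data.frame(data)[idx, , drop = FALSE],
            features = attr(data, "features"),
            class = c("survival_data", "data.frame"))
}

#' @export
print.case_run <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0(
    "case_run (horizon %d, seed %d)\n",
    "  augmented class ratio : %.4f\n",
    "  ECE  raw -> calibrated: %.4f -> %.4f (M = %d bins)\n",
    "  mAUSC  CASE / KM      : %.4f / %.4f\n",
    "  windowed accuracy     : threshold %.3f | gradient %.3f | regression %.3f\n"),
    x$horizon, x$seed, m$class_ratio, m$ece_uncalibrated, m$ece_calibrated,
    x$bins, m$mausc_case, m$mausc_km,
    m$windowed_accuracy["threshold"], m$windowed_accuracy["gradient"],
    m$windowed_accuracy["regression"]))
  invisible(x)
}

#' Compare individual curves against classical survival baselines
#'
#' Thin wrappers around established survival-analysis tooling: Cox
#' proportional hazards (\code{survival::coxph}) and a random survival
#' forest (\code{ranger}) produce their own curves on the test set, and all
#' models are scored with Harrell's C-index (\code{survival::concordance};
#' higher risk = shorter predicted survival) and mAUSC. The KM population
#' baseline has no C-index — a single population curve cannot rank
#' subjects.
#'
#' @param train,test \code{survival_data} objects.
#' @param case_curves the test-set \code{survival_curves} from the pipeline.
#' @param horizon study horizon.
#' @param seed seed for the forest.
#' @param grid_step quadrature step for mAUSC.
#' @return Data frame with one row per model (\code{CASE}, \code{Cox},
#'   \code{RSF}, \code{KM}) and columns \code{c_index}, \code{mausc}.
#' @export
evaluate_against_baselines <- function(train, test, case_curves, horizon,
                                       seed = 1L, grid_step = 0.01) {
  feats <- attr(train, "features")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(feats, collapse = " + ")))
  tr <- as.data.frame(train)
  te <- as.data.frame(test)

  cindex_from_risk <- function(risk) {
    # concordance of risk score vs observed survival (higher risk, earlier event)
    cf <- survival::concordance(survival::Surv(te$time, te$event) ~ risk,
                                reverse = TRUE)
    as.numeric(cf$concordance)
  }
  curve_mausc <- function(curves) {
    as.numeric(mausc(curves, test, grid_step = grid_step))
  }

  rows <- list()
  # CASE: risk = 1 - mean curve height
  rows$CASE <- c(c_index = cindex_from_risk(1 - rowMeans(case_curves)),
                 mausc = curve_mausc(case_curves))
  # Cox
  cox <- survival::coxph(fml, data = tr)
  sf <- survival::survfit(cox, newdata = te)
  cox_curves <- survival_curves(
    vapply(seq_len(horizon), function(tau) {
      as.numeric(summary(sf, times = tau, extend = TRUE)$surv)
    }, numeric(nrow(te))),
    ids = te$id)
  rows$Cox <- c(c_index = cindex_from_risk(stats::predict(cox, newdata = te,
                                                          type = "risk")),
                mausc = curve_mausc(cox_curves))
  # RSF via ranger survival forest
  rsf <- ranger::ranger(fml, data = tr, num.trees = 200, seed = seed,
                        num.threads = 1)
  pr <- stats::predict(rsf, data = te, num.threads = 1)
  rsf_step <- t(vapply(seq_len(nrow(te)), function(i) {
    stats::approx(x = c(0, pr$unique.death.times),
                  y = c(1, pr$survival[i, ]), xout = seq_len(horizon),
                  method = "constant", rule = 2)$y
  }, numeric(horizon)))
  rsf_curves <- survival_curves(rsf_step, ids = te$id)
  rows$RSF <- c(c_index = cindex_from_risk(-rowMeans(rsf_curves)),
                mausc = curve_mausc(rsf_curves))
  # KM population baseline: no C-index (single curve)
  km <- km_baseline(train)
  rows$KM <- c(c_index = NA_real_,
               mausc = curve_mausc(km_curve_matrix(km, horizon, te$id)))

  out <- as.data.frame(do.call(rbind, rows))
  out$model <- names(rows)
  out[c("model", "c_index", "mausc")]
}
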