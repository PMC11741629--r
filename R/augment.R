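#' Person-period augmentation of a survival dataset
#'
#' Applies the transformation operator that turns censored time-to-event data
#' into a binary classification problem. Each subject is replicated into one
#' row per discrete period \code{tau}:
#' \itemize{
#'   \item an event record (\code{event = 1}) contributes exactly \code{P}
#'     rows, \code{tau = 1..P}, labelled \code{1} ("survived period tau")
#'     for \code{tau <= floor_periods(time)} (capped at \code{P}) and
#'     \code{0} afterwards;
#'   \item a censored record (\code{event = 0}) contributes
#'     \code{min(P, floor_periods(time))} rows, all labelled \code{1} —
#'     nothing is claimed beyond the observed follow-up.
#' }
#' A censored record with less than one complete period contributes no rows.
#' Covariate values are copied unchanged to every replicate, and the period
#' index is appended as a feature, so a classifier fitted on the result
#' predicts period-specific survival.
#'
#' @param data a \code{\link{as_survival_data}} object.
#' @param horizon positive integer \code{P}, the study horizon in periods.
#' @return A data frame of class \code{"case_augmented"} with columns
#'   \code{source_id}, \code{period}, \code{label}, then the covariates.
#'   Rows are ordered by source record, then period ascending. Attributes:
#'   \code{horizon}, \code{features}.
#' @examples
#' d <- as_survival_data(data.frame(id = c("cens", "evt"), time = c(6, 6),
#'                                  event = c(0, 1), x = c(1, 2)))
#' a <- case_augment(d, horizon = 20)
#' table(a$source_id, a$label)  # cens: 6 positives; evt: 6 pos + 14 neg
#' @export
case_augment <- function(data, horizon) {
  stopifnot(inherits(data, "survival_data"))
  horizon <- check_horizon(horizon)
  feats <- attr(data, "features")

  fp <- pmin(floor_periods(data$time), horizon)
  n_rows <- ifelse(data$event == 1, horizon, fp)
  idx <- rep.int(seq_len(nrow(data)), n_rows)
  period <- sequence(n_rows)
  label <- as.integer(period <= fp[idx])

  out <- data.frame(source_id = data$id[idx],
                    period = as.integer(period),
                    label = label,
                    as.data.frame(data)[idx, feats, drop = FALSE],
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("source_id", "period", "label", feats)
  rownames(out) <- NULL
  structure(out, horizon = horizon, features = feats,
            class = c("case_augmented", "data.frame"))
}

check_horizon <- function(horizon) {
  if (length(horizon) != 1L || !is.finite(horizon) || horizon < 1 ||
      horizon != floor(horizon)) {
    stop("horizon must be a single positive integer")
  }
  as.integer(horizon)
}

#' Positive class ratio of the augmented dataset
#'
#' Closed-form fraction of positive ("survived") rows the augmentation
#' produces: every record — event or censored — contributes
#' \code{min(floor_periods(time), P)} positive rows, and event records add
#' \code{P - min(floor_periods(time), P)} negative rows, so the ratio is
#' the summed positive counts over the total augmented size. Equals the
#' empirical positive fraction of \code{\link{case_augment}} on the same
#' inputs.
#'
#' @inheritParams case_augment
#' @return A single number in \code{[0, 1]}.
#' @export
case_class_ratio <- function(data, horizon) {
  stopifnot(inherits(data, "survival_data"))
  horizon <- check_horizon(horizon)
  fp <- pmin(floor_periods(data$time), horizon)
  total <- sum(ifelse(data$event == 1, horizon, fp))
  if (total == 0) {
    stop("augmented dataset is empty; class ratio undefined")
  }
  sum(fp) / total
}

#' Expand records over the horizon for prediction
#'
#' At prediction time the future is unknown, so each record is propagated
#' through the model once per period: \code{P} unlabeled rows with
#' \code{tau = 1..P} and the covariates copied unchanged.
#'
#' @param newdata a \code{survival_data} object or a plain data frame of
#'   covariates (one row per subject; an \code{id} column is used if
#'   present, otherwise row numbers).
#' @inheritParams case_augment
#' @return A data frame with columns \code{source_id}, \code{period}, then
#'   covariates; \code{P} rows per input record, period ascending.
#' @export
expand_for_prediction <- function(newdata, horizon) {
  horizon <- check_horizon(horizon)
  if (inherits(newdata, "survival_data")) {
    feats <- attr(newdata, "features")
    ids <- newdata$id
    covs <- as.data.frame(newdata)[feats]
  } else {
    newdata <- as.data.frame(newdata)
    ids <- if ("id" %in% names(newdata)) as.character(newdata$id) else
      as.character(seq_len(nrow(newdata)))
    feats <- setdiff(names(newdata), c("id", "time", "event"))
    covs <- newdata[feats]
  }
  idx <- rep.int(seq_along(ids), rep.int(horizon, length(ids)))
  out <- data.frame(source_id = ids[idx],
                    period = rep.int(seq_len(horizon), length(ids)),
                    covs[idx, , drop = FALSE],
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("source_id", "period", feats)
  rownames(out) <- NULL
  structure(out, horizon = horizon, features = feats,
            class = c("case_expanded", "data.frame"))
}

#' De-augmentation: append per-period survival probabilities as features
#'
#' Builds the regression design table: one row per subject containing the
#' original covariates followed by the \code{P} calibrated survival
#' probabilities of that subject's curve, ordered by period. This is the
#' training table for the regression-based survival-time estimator.
#'
#' @param data a \code{survival_data} object.
#' @param curves a \code{\link{survival_curves}} matrix (subjects x periods)
#'   whose rownames cover every subject id in \code{data}.
#' @return A data frame of class \code{"case_survival_table"}: columns
#'   \code{id}, the covariates, then \code{prob_1..prob_P}; subject order
#'   as in \code{data}.
#' @export
attach_survival_features <- function(data, curves) {
  stopifnot(inherits(data, "survival_data"))
  P <- attr(curves, "horizon")
  if (is.null(P)) P <- ncol(curves)
  if (ncol(curves) != P) {
    stop("curve length ", ncol(curves), " does not match horizon ", P)
  }
  missing_ids <- setdiff(data$id, rownames(curves))
  if (length(missing_ids) > 0L) {
    stop("no survival curve for subject(s): ",
         paste(utils::head(missing_ids, 5L), collapse = ", "))
  }
  feats <- attr(data, "features")
  probs <- curves[data$id, , drop = FALSE]
  out <- data.frame(id = data$id,
                    as.data.frame(data)[feats],
                    probs,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("id", feats, paste0("prob_", seq_len(P)))
  rownames(out) <- NULL
  structure(out, features = feats, horizon = P,
            class = c("case_survival_table", "data.frame"))
}

#' Write an augmented dataset as CSV
#'
#' Columns \code{source_id,period,label,<features...>}.
#' @param augmented a \code{case_augmented} data frame.
#' @param path file path.
#' @export
write_augmented_csv <- function(augmented, path) {
  utils::write.csv(as.data.frame(augmented), path, row.names = FALSE)
  invisible(path)
}
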