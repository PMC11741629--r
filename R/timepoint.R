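#' Threshold-based survival-time estimate
#'
#' The subject is considered to survive period \code{tau} while the curve
#' stays above the threshold; the estimate is the latest period at which it
#' does, \code{max\{tau : S_i(tau) > theta\}}. Returns 0 when no period
#' clears the threshold and \code{P} when all do.
#'
#' @param curves a \code{\link{survival_curves}} matrix (or a single numeric
#'   curve vector).
#' @param theta threshold in (0, 1), default 0.5.
#' @return Integer vector (one estimate per subject) in \code{0..P}, named
#'   by subject id.
#' @export
estimate_time_threshold <- function(curves, theta = 0.5) {
  if (length(theta) != 1L || theta <= 0 || theta >= 1) {
    stop("theta must lie strictly inside (0, 1)")
  }
  m <- curve_matrix(curves)
  est <- apply(m, 1L, function(p) {
    above <- which(p > theta)
    if (length(above) == 0L) 0L else max(above)
  })
  stats::setNames(as.integer(est), rownames(m))
}

#' Gradient-based survival-time estimate
#'
#' Locates the steepest one-period decline of the curve: the estimate is the
#' period \code{tau} (2..P) on which the largest drop
#' \code{S(tau - 1) - S(tau)} lands, interpreting the sharpest fall in
#' survival probability as the most likely event period. Ties break toward
#' the earliest period; a curve with no decline anywhere returns \code{P}.
#'
#' @inheritParams estimate_time_threshold
#' @return Integer vector in \code{1..P}, named by subject id.
#' @export
estimate_time_gradient <- function(curves) {
  m <- curve_matrix(curves)
  if (ncol(m) < 2L) stop("gradient estimation needs a horizon of at least 2")
  est <- apply(m, 1L, function(p) {
    drops <- p[-length(p)] - p[-1L]
    if (max(drops) <= 0) return(length(p))
    # earliest period within numerical tolerance of the steepest drop
    which(drops >= max(drops) - 1e-9)[1L] + 1L
  })
  stats::setNames(as.integer(est), rownames(m))
}

curve_matrix <- function(curves) {
  if (is.matrix(curves)) curves else matrix(curves, nrow = 1L,
                                            dimnames = list("1", NULL))
}

#' Regression-based survival-time estimator
#'
#' Fits a regressor on the de-augmented table (original covariates plus the
#' \code{P} per-period survival probabilities,
#' \code{\link{attach_survival_features}}), restricted to event subjects —
#' the only ones whose true survival time is observed. Censored subjects are
#' excluded from fitting but can be predicted afterwards. The default family
#' is a gradient-boosted tree regressor with a fixed seed; \code{"linear"}
#' uses ordinary least squares.
#'
#' @param survival_table a \code{case_survival_table} from
#'   \code{\link{attach_survival_features}}.
#' @param data the matching \code{survival_data} object (supplies times and
#'   event indicators).
#' @param family \code{"xgboost"} or \code{"linear"}.
#' @param seed integer seed for the boosted regressor.
#' @param nrounds,max_depth,eta boosted-regressor settings.
#' @return An object of class \code{"case_time_regressor"}.
#' @export
fit_time_regressor <- function(survival_table, data,
                               family = c("xgboost", "linear"), seed = 1L,
                               nrounds = 200, max_depth = 4, eta = 0.1) {
  family <- match.arg(family)
  stopifnot(inherits(data, "survival_data"))
  ev <- data$event == 1
  if (!any(ev)) stop("cannot fit the survival-time regressor: no event records")
  predictors <- setdiff(names(survival_table), "id")
  tab <- survival_table[match(data$id, survival_table$id), , drop = FALSE]
  x <- as.matrix(as.data.frame(tab)[predictors])
  storage.mode(x) <- "double"
  y <- data$time
  set.seed(seed)
  fitted <- if (family == "xgboost") {
    xgboost::xgb.train(
      params = list(objective = "reg:squarederror", max_depth = max_depth,
                    eta = eta, nthread = 1, seed = seed),
      data = xgboost::xgb.DMatrix(x[ev, , drop = FALSE], label = y[ev]),
      nrounds = nrounds, verbose = 0)
  } else {
    df <- data.frame(.time = y[ev], x[ev, , drop = FALSE], check.names = FALSE)
    stats::lm(.time ~ ., data = df)
  }
  structure(list(family = family, fitted = fitted, predictors = predictors),
            class = "case_time_regressor")
}

#' Predict exact survival times
#'
#' @param object a fitted \code{case_time_regressor}.
#' @param survival_table rows to predict (same schema as used for fitting).
#' @param ... unused.
#' @return Numeric vector of predicted survival times, named by subject id.
#'   Predictions are real-valued and not clipped.
#' @export
predict.case_time_regressor <- function(object, survival_table, ...) {
  missing_cols <- setdiff(object$predictors, names(survival_table))
  if (length(missing_cols) > 0L) {
    stop("schema mismatch; missing predictor(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(as.data.frame(survival_table)[object$predictors])
  storage.mode(x) <- "double"
  pred <- if (object$family == "xgboost") {
    as.numeric(stats::predict(object$fitted, xgboost::xgb.DMatrix(x)))
  } else {
    as.numeric(stats::predict(object$fitted,
                              newdata = as.data.frame(x)))
  }
  stats::setNames(pred, survival_table$id)
}

#' Windowed survival-time prediction accuracy
#'
#' Fraction of (event) subjects whose predicted survival time falls within a
#' window of the true time. A "five-year window" reads most naturally as a
#' window of total width 5 centered on the prediction, i.e.
#' \code{|error| <= window / 2} (the default); \code{mode = "full"} uses the
#' looser \code{|error| <= window} reading instead.
#'
#' @param predicted,actual equal-length numeric vectors of survival times.
#' @param window window width in periods (default 5).
#' @param mode \code{"half"} (\code{|err| <= window/2}) or \code{"full"}
#'   (\code{|err| <= window}).
#' @return Fraction in \code{[0, 1]}.
#' @export
windowed_accuracy <- function(predicted, actual, window = 5,
                              mode = c("half", "full")) {
  mode <- match.arg(mode)
  stopifnot(length(predicted) == length(actual))
  if (length(predicted) == 0L) stop("empty input")
  tol <- if (mode == "half") window / 2 else window
  mean(abs(predicted - actual) <= tol)
}
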