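#' Individual survival curves from calibrated per-period scores
#'
#' A \code{survival_curves} object is a numeric matrix, one row per subject
#' and one column per period \code{tau = 1..P}, holding the calibrated
#' survival probabilities \code{S_i(tau)}. Curves are deliberately NOT
#' forced to be monotone non-increasing: period-specific classification can
#' legitimately express non-monotone risk (e.g. a late survival bump) that
#' population product-limit curves cannot.
#'
#' @param probs numeric matrix (subjects x periods) with values in [0, 1].
#' @param ids character vector of subject ids (rownames).
#' @return The matrix with class \code{"survival_curves"} and attribute
#'   \code{horizon}.
#' @export
survival_curves <- function(probs, ids = rownames(probs)) {
  probs <- as.matrix(probs)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(probs)))
  stopifnot(length(ids) == nrow(probs))
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("curve probabilities must be finite and in [0, 1]")
  }
  rownames(probs) <- as.character(ids)
  colnames(probs) <- paste0("tau_", seq_len(ncol(probs)))
  structure(probs, horizon = ncol(probs),
            class = c("survival_curves", "matrix", "array"))
}

#' Predict individual survival curves
#'
#' Expands each record over the horizon (\code{\link{expand_for_prediction}}),
#' scores every (record, period) row with the fitted classifier, calibrates
#' the raw scores through the ABBQ map, and reshapes the result into one
#' curve per subject.
#'
#' @param model a fitted \code{\link{case_classifier}}.
#' @param map an \code{"abbq"} calibration map, or \code{NULL} to return raw
#'   classifier scores uncalibrated.
#' @param newdata a \code{survival_data} object or covariate data frame.
#' @param horizon study horizon \code{P}; defaults to the model's.
#' @return A \code{\link{survival_curves}} matrix.
#' @export
predict_curves <- function(model, map, newdata, horizon = model$horizon) {
  expanded <- expand_for_prediction(newdata, horizon)
  raw <- score_classifier(model, expanded)
  cal <- if (is.null(map)) raw else predict(map, raw)
  ids <- unique(expanded$source_id)
  probs <- matrix(cal, nrow = length(ids), ncol = horizon, byrow = TRUE)
  survival_curves(probs, ids = ids)
}

#' Interpolate a survival curve at arbitrary real times
#'
#' Curves are defined at integer periods; between them the survival
#' probability is linearly interpolated. By convention \code{S(0) = 1}
#' (everyone is alive at the origin), so on \code{[0, 1)} the curve
#' interpolates from 1 down to \code{S(1)}. At integer \code{t} the stored
#' value is returned exactly. Times outside \code{[0, P]} are a range error:
#' the curves carry no information beyond the horizon.
#'
#' @param curve numeric vector of length \code{P} (one subject's curve), or
#'   a single row of a \code{survival_curves} matrix.
#' @param t numeric vector of times in \code{[0, P]}.
#' @return Numeric vector of interpolated probabilities.
#' @examples
#' interpolate_curve(c(0.9, 0.8, 0.6), c(0, 0.5, 2, 2.5))
#' @export
interpolate_curve <- function(curve, t) {
  curve <- as.numeric(curve)
  P <- length(curve)
  if (any(t < 0 | t > P)) {
    stop(sprintf("interpolation time outside [0, %d]", P))
  }
  stats::approx(x = 0:P, y = c(1, curve), xout = t, method = "linear")$y
}

#' Kaplan-Meier population baseline
#'
#' Product-limit estimate of the population survival function:
#' \code{S(t) = prod over event times t_j <= t of (1 - d_j / n_j)}, where
#' \code{d_j} events occur at \code{t_j} among \code{n_j} subjects still at
#' risk. Censored subjects leave the risk set after their censoring time.
#' This is the single-curve population comparator for the individual curves.
#'
#' @param data a \code{survival_data} object.
#' @return An object of class \code{"km_curve"}: list with \code{time}
#'   (distinct event times), \code{surv} (survival just after each), and
#'   \code{step} (a right-continuous step function usable as
#'   \code{object$step(t)}).
#' @examples
#' d <- as_survival_data(data.frame(id = 1:5, time = c(1, 2, 3, 4, 5),
#'                                  event = c(1, 0, 1, 0, 0)))
#' km <- km_baseline(d)
#' km$step(c(1, 3))  # 4/5, 8/15
#' @export
km_baseline <- function(data) {
  stopifnot(inherits(data, "survival_data"))
  if (nrow(data) == 0L) stop("empty dataset")
  tt <- sort(unique(data$time[data$event == 1]))
  if (length(tt) == 0L) {
    surv <- numeric(0)
  } else {
    at_risk <- vapply(tt, function(u) sum(data$time >= u), numeric(1))
    deaths <- vapply(tt, function(u) sum(data$time == u & data$event == 1),
                     numeric(1))
    surv <- cumprod(1 - deaths / at_risk)
  }
  step <- stats::stepfun(c(0, tt), c(1, 1, surv), right = FALSE)
  structure(list(time = tt, surv = surv, step = step), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier baseline: %d distinct event times, S(max) = %.4f\n",
              length(x$time), if (length(x$surv)) min(x$surv) else 1))
  invisible(x)
}

#' Population curve matrix from a KM baseline
#'
#' Evaluates the KM step function at periods \code{1..P} and replicates it
#' for each requested subject, so the population baseline can be scored with
#' the same per-subject metrics as individual curves.
#'
#' @param km a \code{"km_curve"} object.
#' @param horizon number of periods \code{P}.
#' @param ids subject ids to replicate for.
#' @return A \code{\link{survival_curves}} matrix.
#' @export
km_curve_matrix <- function(km, horizon, ids) {
  s <- km$step(seq_len(horizon))
  survival_curves(matrix(rep(s, each = length(ids)), nrow = length(ids)),
                  ids = ids)
}

#' Write curves as long-format CSV
#'
#' Columns \code{subject_id,period,probability}.
#' @param curves a \code{survival_curves} matrix.
#' @param path file path.
#' @export
write_curves_csv <- function(curves, path) {
  P <- ncol(curves)
  long <- data.frame(subject_id = rep(rownames(curves), each = P),
                     period = rep(seq_len(P), times = nrow(curves)),
                     probability = as.vector(t(curves)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
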