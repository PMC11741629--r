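#' Ideal sigmoid survival curve
#'
#' The ideal prediction for a subject with event time \code{T_i} is the step
#' function 1 up to the event and 0 after; its continuous relaxation is a
#' decreasing sigmoid passing through 0.5 exactly at \code{T_i},
#' \deqn{S(t) = \frac{1}{1 + e^{M_s (t - T_i)}},}
#' with steepness \code{M_s} controlling how sharply survival and
#' non-survival separate (the step function is the \code{M_s -> Inf} limit).
#'
#' @param event_time event time \code{T_i}.
#' @param steepness positive steepness \code{M_s}.
#' @return A function of \code{t} returning survival probabilities.
#' @examples
#' f <- ideal_curve(10, steepness = 2)
#' f(10)  # exactly 0.5
#' @export
ideal_curve <- function(event_time, steepness) {
  stopifnot(steepness > 0)
  force(event_time); force(steepness)
  function(t) 1 / (1 + exp(steepness * (t - event_time)))
}

#' Exponential time weight around the event
#'
#' Accuracy near the true event time matters most; deviations are weighted
#' by \code{w(t) = exp(-|t - T_i| / P)}, which is 1 at the event time and
#' decays to \code{exp(-1)} at distance \code{P}. Event times beyond the
#' horizon are capped at \code{P} before the distance is taken.
#'
#' @param t numeric vector of times.
#' @param event_time event time \code{T_i}.
#' @param horizon study horizon \code{P}.
#' @return Numeric vector of weights in \code{(0, 1]}.
#' @export
ausc_weight <- function(t, event_time, horizon) {
  stopifnot(horizon >= 1)
  exp(-abs(t - min(event_time, horizon)) / horizon)
}

#' Individual area under the survival curve (iAUSC)
#'
#' Scores one subject's predicted survival curve against the observed event:
#' the time-weighted mean absolute deviation between the prediction and the
#' ideal step function \code{1[t <= T_i]},
#' \deqn{E_i = \frac{\int_0^P |\hat S(t) - 1[t \le T_i]|\, w(t)\, dt}
#'                  {\int_0^P w(t)\, dt},}
#' is computed by trapezoidal quadrature on a fine grid and reported as the
#' score \code{1 - E_i} so that higher is better (a perfect step predictor
#' scores 1, a constant 0.5 predictor scores exactly 0.5). The raw weighted
#' error is attached as attribute \code{"error"}. Only evaluable for event
#' subjects: a censored subject has no observed \code{T_i}.
#'
#' @param curve one subject's curve: numeric vector of \code{P} per-period
#'   probabilities (interpolated linearly, \code{S(0) = 1}), or a function
#'   of \code{t}.
#' @param event_time observed event time \code{T_i} (may exceed the horizon;
#'   the weight caps it at \code{P}).
#' @param horizon study horizon \code{P}; required when \code{curve} is a
#'   function.
#' @param grid_step quadrature step in periods (default 0.01).
#' @return Score in \code{[0, 1]} with attribute \code{"error"}.
#' @examples
#' step_pred <- function(t) as.numeric(t <= 10)
#' iausc(step_pred, event_time = 10, horizon = 20)  # ~1
#' @export
iausc <- function(curve, event_time, horizon = NULL, grid_step = 0.01) {
  if (is.na(event_time)) {
    stop("iAUSC requires an observed event time; censored subjects are not evaluable")
  }
  if (is.function(curve)) {
    if (is.null(horizon)) stop("horizon must be given for a functional curve")
    shat <- curve
  } else {
    curve <- as.numeric(curve)
    if (is.null(horizon)) horizon <- length(curve)
    shat <- function(t) interpolate_curve(curve, t)
  }
  P <- horizon
  # integrate each side of the step separately so the discontinuity at T_i
  # never falls inside a trapezoid
  Tc <- min(event_time, P)
  seg_grid <- function(a, b) unique(c(seq(a, b, by = grid_step), b))
  num <- 0
  if (Tc > 0) {
    g <- seg_grid(0, Tc)
    num <- num + trapz(g, abs(shat(g) - 1) * ausc_weight(g, event_time, P))
  }
  if (Tc < P) {
    g <- seg_grid(Tc, P)
    num <- num + trapz(g, abs(shat(g)) * ausc_weight(g, event_time, P))
  }
  gw <- sort(unique(c(seq(0, P, by = grid_step), Tc, P)))
  den <- trapz(gw, ausc_weight(gw, event_time, P))
  err <- num / den
  structure(1 - err, error = err)
}

trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Mean area under the survival curve (mAUSC)
#'
#' Dataset-level curve accuracy: the arithmetic mean of \code{\link{iausc}}
#' over the event subjects only. Censored subjects are excluded — their true
#' event time is unobserved, so no weighting by the censoring distribution
#' is needed.
#'
#' @param curves a \code{\link{survival_curves}} matrix covering every event
#'   subject in \code{data}.
#' @param data a \code{survival_data} object.
#' @param grid_step quadrature step passed to \code{\link{iausc}}.
#' @return The mean score, with per-subject scores as attribute
#'   \code{"iausc"} (named by subject id).
#' @export
mausc <- function(curves, data, grid_step = 0.01) {
  stopifnot(inherits(data, "survival_data"))
  ev <- data[data$event == 1, , drop = FALSE]
  if (nrow(ev) == 0L) stop("mAUSC requires at least one event subject")
  missing_ids <- setdiff(ev$id, rownames(curves))
  if (length(missing_ids) > 0L) {
    stop("no curve for event subject(s): ",
         paste(utils::head(missing_ids, 5L), collapse = ", "))
  }
  scores <- vapply(seq_len(nrow(ev)), function(k) {
    as.numeric(iausc(curves[ev$id[k], ], event_time = ev$time[k],
                     horizon = ncol(curves), grid_step = grid_step))
  }, numeric(1))
  names(scores) <- ev$id
  structure(mean(scores), iausc = scores)
}

#' Expected calibration error
#'
#' Bins predicted probabilities into equal-width bins over \code{[0, 1]} and
#' returns the occupancy-weighted mean absolute gap between the mean
#' predicted probability and the observed outcome rate per bin,
#' \code{sum_b (n_b / n) |mean(p_b) - mean(y_b)|}.
#'
#' @param probabilities predicted probabilities in \code{[0, 1]}.
#' @param outcomes binary outcomes of the same length.
#' @param bins number of equal-width bins (default 10).
#' @return ECE in \code{[0, 1]}.
#' @export
ece <- function(probabilities, outcomes, bins = 10L) {
  stopifnot(length(probabilities) == length(outcomes),
            length(probabilities) > 0L)
  b <- pmin(pmax(ceiling(probabilities * bins), 1L), bins)
  n <- length(probabilities)
  gaps <- vapply(split(seq_len(n), b), function(ix) {
    length(ix) / n * abs(mean(probabilities[ix]) - mean(outcomes[ix]))
  }, numeric(1))
  sum(gaps)
}
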