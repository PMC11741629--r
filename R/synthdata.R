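#' Configuration for the synthetic survival-data generator
#'
#' Defines a discrete-time survival mechanism with known ground truth. Each
#' subject draws standard-normal covariates; the per-period hazard is a
#' logistic function of a period-specific baseline plus (possibly
#' time-varying) covariate effects,
#' \deqn{h_i(\tau) = \mathrm{logit}^{-1}\!\big(\alpha_\tau +
#'       \sum_j \beta_{j,\tau} x_{ij}\big),}
#' the event period is sampled from that hazard, and administrative
#' censoring truncates follow-up at a subject-specific entry-dependent time
#' (a registry's "transplanted x years before the data freeze"). This is the
#' structure the period-replicated classification approach assumes:
#' covariate-dependent hazards, time-varying effects, entry-time censoring
#' and heavy class imbalance at long horizons.
#'
#' @param n number of subjects.
#' @param n_features number of covariates (named \code{x1..xF}).
#' @param horizon study horizon \code{P} (periods of interest).
#' @param baseline per-period baseline log-odds \code{alpha_tau}: scalar
#'   (recycled) or vector of length \code{max_periods}.
#' @param effects covariate effects \code{beta_{j,tau}}: scalar, length-F
#'   vector (constant over time), or F x \code{max_periods} matrix for
#'   time-varying effects.
#' @param max_periods how many periods the hazard mechanism extends over
#'   (defaults to \code{2 * horizon}); events later than this are treated as
#'   beyond observation.
#' @param followup_min,followup_max administrative follow-up window:
#'   censoring times are drawn uniformly (continuously) between the two.
#'   With \code{followup_min >= max_periods} no administrative censoring
#'   occurs within the mechanism's range.
#' @param dropout_rate optional per-period random dropout probability
#'   (default 0, administrative censoring only).
#' @return A list of class \code{"synth_config"}.
#' @export
synth_config <- function(n = 1000L, n_features = 4L, horizon = 10L,
                         baseline = -2.2, effects = 0.8,
                         max_periods = 2L * horizon,
                         followup_min = 1, followup_max = max_periods,
                         dropout_rate = 0) {
  horizon <- check_horizon(horizon)
  max_periods <- check_horizon(max_periods)
  alpha <- rep_len(as.numeric(baseline), max_periods)
  beta <- effects
  if (is.matrix(beta)) {
    stopifnot(nrow(beta) == n_features, ncol(beta) == max_periods)
  } else {
    beta <- matrix(rep_len(as.numeric(beta), n_features), nrow = n_features,
                   ncol = max_periods)
  }
  rownames(beta) <- paste0("x", seq_len(n_features))
  stopifnot(followup_min >= 0, followup_max >= followup_min,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(n = as.integer(n), n_features = as.integer(n_features),
                 horizon = horizon, max_periods = max_periods,
                 alpha = alpha, beta = beta,
                 followup_min = followup_min, followup_max = followup_max,
                 dropout_rate = dropout_rate),
            class = "synth_config")
}

#' Generate a synthetic survival dataset with ground truth
#'
#' Samples the mechanism in a \code{\link{synth_config}}: the observed time
#' is \code{min(T, C)} with event indicator \code{1[T <= C]}, where \code{C}
#' is the (fractional) administrative censoring time and \code{T} the
#' continuous event time — a subject failing the period-\code{tau} hazard
#' draw dies partway through that period, at \code{T in (tau - 1, tau)}, so
#' the completed periods \code{floor(T)} equal the periods actually
#' survived. Subjects whose event falls beyond \code{max_periods} are
#' censored at \code{C}. Returns the true per-subject survival function
#' \code{S_i(tau) = prod_{u <= tau} (1 - h_i(u))} so recovery of the curves
#' can be tested against ground truth.
#'
#' @param config a \code{synth_config}.
#' @param seed integer seed; identical config + seed gives identical data.
#' @return A list: \code{data} (a \code{\link{as_survival_data}} object),
#'   \code{true_surv} (n x horizon matrix of true survival probabilities),
#'   \code{true_time} (true continuous event time, \code{NA} if beyond
#'   \code{max_periods}), \code{hazard} (n x max_periods matrix).
#' @examples
#' g <- generate_survival_data(synth_config(n = 100, horizon = 5), seed = 7)
#' head(g$data)
#' @export
generate_survival_data <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(as.integer(seed))
  n <- config$n
  Pm <- config$max_periods
  x <- matrix(stats::rnorm(n * config$n_features), nrow = n,
              dimnames = list(NULL, rownames(config$beta)))
  eta <- sweep(x %*% config$beta, 2L, config$alpha, `+`)
  hazard <- stats::plogis(eta)                      # n x max_periods
  surv <- t(apply(1 - hazard, 1L, cumprod))         # true S_i(tau)

  u <- matrix(stats::runif(n * Pm), nrow = n)
  event_mat <- u < hazard
  first_event <- apply(event_mat, 1L, function(z) {
    w <- which(z); if (length(w)) w[1L] else NA_integer_
  })
  # a death in period tau happens partway through it: the continuous event
  # time lies in (tau - 1, tau), so the subject has completed tau - 1 periods
  frac <- stats::runif(n)
  cens <- stats::runif(n, config$followup_min, config$followup_max)
  if (config$dropout_rate > 0) {
    drop_u <- matrix(stats::runif(n * Pm), nrow = n)
    first_drop <- apply(drop_u < config$dropout_rate, 1L, function(z) {
      w <- which(z); if (length(w)) w[1L] else NA_integer_
    })
    cens <- pmin(cens, ifelse(is.na(first_drop), Inf, first_drop))
  }
  true_t <- ifelse(is.na(first_event), Inf, first_event - 1 + frac)
  observed <- pmin(true_t, cens)
  delta <- as.integer(true_t <= cens)

  df <- data.frame(id = sprintf("s%05d", seq_len(n)),
                   time = observed, event = delta,
                   as.data.frame(x), stringsAsFactors = FALSE)
  data <- as_survival_data(df)
  list(data = data,
       true_surv = surv[, seq_len(config$horizon), drop = FALSE],
       true_time = ifelse(is.finite(true_t), true_t, NA_real_),
       hazard = hazard)
}

#' Configurations for the two class-imbalance extremes
#'
#' Builds generator configurations for the two canonical censoring regimes
#' that determine how the augmented positive-class ratio responds to the
#' horizon choice:
#' \describe{
#'   \item{\code{minimal_censoring}}{most events occur early and follow-up
#'     comfortably covers the study period, so the class ratio changes
#'     little as the horizon grows;}
#'   \item{\code{censoring_dominance}}{low hazard with short, early
#'     follow-up windows, so most records are censored early and
#'     lengthening the horizon raises the positive-class ratio.}
#' }
#'
#' @param kind \code{"minimal_censoring"} or \code{"censoring_dominance"}.
#' @param n number of subjects.
#' @param horizon study horizon.
#' @return A \code{\link{synth_config}}.
#' @export
imbalance_scenario <- function(kind = c("minimal_censoring",
                                        "censoring_dominance"),
                               n = 2000L, horizon = 20L) {
  kind <- match.arg(kind)
  if (kind == "minimal_censoring") {
    # high early hazard, long follow-up: events dominate
    synth_config(n = n, n_features = 2L, horizon = horizon,
                 baseline = -0.5, effects = 0.3,
                 max_periods = 2L * horizon,
                 followup_min = 2L * horizon, followup_max = 2L * horizon + 1)
  } else {
    # low hazard, early administrative censoring: censoring dominates
    synth_config(n = n, n_features = 2L, horizon = horizon,
                 baseline = -3.5, effects = 0.3,
                 max_periods = 2L * horizon,
                 followup_min = 1, followup_max = horizon / 2)
  }
}
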