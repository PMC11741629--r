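#' Temporal variable importance from per-period SHAP values
#'
#' For each period \code{tau}, additive feature attributions (SHAP values)
#' are computed for the rows \code{(x_i, tau)} of the subjects observed to
#' survive \code{tau} complete periods, the survivor set
#' \code{I_tau = \{i : floor_periods(t_i) >= tau\}}. The importance of
#' feature \code{j} at \code{tau} is the arithmetic mean of those
#' per-subject attributions over \code{I_tau}. Because survivor sets shrink
#' over time, \code{|I_tau|} is non-increasing in \code{tau}.
#'
#' Attributions use the exact tree-path algorithm of the xgboost backend
#' (deterministic, margin/log-odds scale); the contribution of the period
#' feature itself is computed but reported separately from the covariates.
#' To keep the cost manageable on large cohorts, at most
#' \code{max_subjects} subjects are used (a seeded subsample; the cap is
#' reported via a message).
#'
#' @param model a fitted \code{\link{case_classifier}} with the xgboost
#'   backend.
#' @param data the \code{survival_data} the survivor sets are taken from.
#' @param horizon study horizon \code{P} (defaults to the model's).
#' @param max_subjects subsample cap (default 2000).
#' @param seed seed for the subsample.
#' @return An object of class \code{"temporal_importance"}: list with
#'   \code{mean} (features x P matrix of mean attributions, the period
#'   feature and intercept in separate rows \code{".period"} and
#'   \code{".bias"}), \code{n_survivors} (length-P vector of
#'   \code{|I_tau|}), and \code{trajectories} (per-subject attribution
#'   arrays, a list by feature of subjects x P matrices with \code{NA}
#'   beyond each subject's survived periods).
#' @export
temporal_importance <- function(model, data, horizon = model$horizon,
                                max_subjects = 2000L, seed = 1L) {
  stopifnot(inherits(model, "case_classifier"),
            inherits(data, "survival_data"))
  if (model$family != "xgboost") {
    stop("exact tree-path attributions are only available for the xgboost backend")
  }
  horizon <- check_horizon(horizon)
  if (nrow(data) > max_subjects) {
    set.seed(seed)
    keep <- sort(sample.int(nrow(data), max_subjects))
    message(sprintf("temporal_importance: subsampled %d of %d subjects",
                    max_subjects, nrow(data)))
    data <- structure(as.data.frame(data)[keep, , drop = FALSE],
                      features = attr(data, "features"),
                      class = c("survival_data", "data.frame"))
  }
  feats <- attr(data, "features")
  fp <- pmin(floor_periods(data$time), horizon)

  expanded <- expand_for_prediction(data, horizon)
  # survivor rows only: subject i contributes periods 1..floor_periods(t_i)
  surv_rows <- expanded$period <= fp[match(expanded$source_id, data$id)]
  expanded <- expanded[surv_rows, , drop = FALSE]
  x <- design_matrix(model, expanded)
  contrib <- stats::predict(model$fitted, xgboost::xgb.DMatrix(x),
                            predcontrib = TRUE)
  colnames(contrib) <- c(model$feature_names, ".bias")

  n_survivors <- vapply(seq_len(horizon), function(tau) sum(fp >= tau),
                        integer(1))
  mean_mat <- matrix(NA_real_, nrow = length(feats) + 2L, ncol = horizon,
                     dimnames = list(c(feats, ".period", ".bias"),
                                     paste0("tau_", seq_len(horizon))))
  traj <- lapply(stats::setNames(feats, feats), function(j) {
    m <- matrix(NA_real_, nrow = nrow(data), ncol = horizon,
                dimnames = list(data$id, paste0("tau_", seq_len(horizon))))
    m
  })
  per <- expanded$period
  for (tau in seq_len(horizon)) {
    rows <- which(per == tau)
    if (length(rows) == 0L) next
    mean_mat[, tau] <- c(colMeans(contrib[rows, feats, drop = FALSE]),
                         mean(contrib[rows, "period"]),
                         mean(contrib[rows, ".bias"]))
    ids_tau <- expanded$source_id[rows]
    for (j in feats) traj[[j]][ids_tau, tau] <- contrib[rows, j]
  }
  structure(list(mean = mean_mat, n_survivors = n_survivors,
                 trajectories = traj, horizon = horizon),
            class = "temporal_importance")
}

#' @export
print.temporal_importance <- function(x, ...) {
  cat(sprintf("temporal_importance: %d features x %d periods; survivors %d -> %d\n",
              nrow(x$mean) - 2L, x$horizon, x$n_survivors[1L],
              x$n_survivors[x$horizon]))
  invisible(x)
}

#' Individual importance trajectory
#'
#' One subject's attribution for one feature across the periods they were
#' observed to survive. The mean of all subjects' trajectories at a period
#' equals the population profile at that period by construction.
#'
#' @param profile a \code{\link{temporal_importance}} object.
#' @param subject_id subject identifier.
#' @param feature covariate name.
#' @return Numeric vector over \code{tau = 1..floor_periods(t_i)}.
#' @export
individual_trajectory <- function(profile, subject_id, feature) {
  if (!feature %in% names(profile$trajectories)) {
    stop("unknown feature: ", feature)
  }
  m <- profile$trajectories[[feature]]
  if (!subject_id %in% rownames(m)) stop("unknown subject: ", subject_id)
  v <- m[subject_id, ]
  v[!is.na(v)]
}

#' Write a temporal importance profile as CSV
#'
#' Columns \code{feature,period,mean_shap,n_survivors}.
#' @param profile a \code{temporal_importance} object.
#' @param path file path.
#' @export
write_importance_csv <- function(profile, path) {
  feats <- rownames(profile$mean)
  P <- profile$horizon
  long <- data.frame(feature = rep(feats, each = P),
                     period = rep(seq_len(P), times = length(feats)),
                     mean_shap = as.vector(t(profile$mean)),
                     n_survivors = rep(profile$n_survivors, times = length(feats)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
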