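#' Classifier adapter for the augmented classification problem
#'
#' Wraps a binary classifier behind a uniform fit/score contract so the
#' survival pipeline is agnostic to the model family. The design matrix is
#' the covariates plus the period index \code{tau} as an ordinary numeric
#' feature; the score is the predicted probability of the positive
#' ("survived") class. Both backends are tree ensembles, the family the
#' period-replicated formulation works best with:
#' \describe{
#'   \item{\code{xgboost}}{gradient-boosted trees (default). Deterministic
#'     for a fixed seed and single thread, and supports exact tree-path SHAP
#'     attributions used by \code{\link{temporal_importance}}.}
#'   \item{\code{random_forest}}{a \pkg{ranger} probability forest.}
#' }
#'
#' @param family \code{"xgboost"} or \code{"random_forest"}.
#' @param nrounds,max_depth,eta xgboost defaults (boosting rounds, tree
#'   depth, learning rate).
#' @param num_trees ranger default.
#' @param ... further arguments passed to the backend.
#' @return An unfitted adapter of class \code{"case_classifier"}; fit with
#'   \code{\link{fit_classifier}}.
#' @export
case_classifier <- function(family = c("xgboost", "random_forest"),
                            nrounds = 150, max_depth = 4, eta = 0.2,
                            num_trees = 300, ...) {
  family <- match.arg(family)
  structure(list(family = family, fitted = NULL, feature_names = NULL,
                 horizon = NULL,
                 params = list(nrounds = nrounds, max_depth = max_depth,
                               eta = eta, num_trees = num_trees,
                               extra = list(...))),
            class = "case_classifier")
}

design_matrix <- function(adapter_or_feats, table) {
  feats <- if (is.character(adapter_or_feats)) adapter_or_feats else
    adapter_or_feats$feature_names
  missing_cols <- setdiff(feats, names(table))
  if (length(missing_cols) > 0L) {
    stop("feature schema mismatch; missing: ",
         paste(missing_cols, collapse = ", "))
  }
  m <- as.matrix(as.data.frame(table)[feats])
  storage.mode(m) <- "double"
  m
}

#' Fit the classifier on an augmented dataset
#'
#' @param adapter a \code{\link{case_classifier}}.
#' @param augmented a \code{case_augmented} data frame (label, period,
#'   covariates).
#' @param seed integer seed; fitting is deterministic given the seed (the
#'   xgboost backend additionally runs single-threaded so results do not
#'   depend on scheduling).
#' @return The fitted adapter.
#' @export
fit_classifier <- function(adapter, augmented, seed = 1L) {
  stopifnot(inherits(adapter, "case_classifier"))
  feats <- c(attr(augmented, "features"), "period")
  adapter$feature_names <- feats
  adapter$horizon <- attr(augmented, "horizon")
  x <- design_matrix(feats, augmented)
  y <- augmented$label
  set.seed(seed)
  if (adapter$family == "xgboost") {
    dtrain <- xgboost::xgb.DMatrix(x, label = y)
    adapter$fitted <- xgboost::xgb.train(
      params = c(list(objective = "binary:logistic", max_depth = adapter$params$max_depth,
                      eta = adapter$params$eta, nthread = 1,
                      seed = seed),
                 adapter$params$extra),
      data = dtrain, nrounds = adapter$params$nrounds, verbose = 0)
  } else {
    df <- data.frame(x, .label = factor(y, levels = c(0, 1)),
                     check.names = FALSE)
    adapter$fitted <- ranger::ranger(
      dependent.variable.name = ".label", data = df, probability = TRUE,
      num.trees = adapter$params$num_trees, seed = seed, num.threads = 1)
  }
  adapter
}

#' Raw survival scores for (record, period) rows
#'
#' @param adapter a fitted \code{case_classifier}.
#' @param table a data frame carrying the covariates and a \code{period}
#'   column (e.g. from \code{\link{expand_for_prediction}}).
#' @return Numeric vector of raw positive-class probabilities in [0, 1].
#' @export
score_classifier <- function(adapter, table) {
  if (is.null(adapter$fitted)) stop("classifier has not been fitted")
  x <- design_matrix(adapter, table)
  if (adapter$family == "xgboost") {
    as.numeric(stats::predict(adapter$fitted, xgboost::xgb.DMatrix(x)))
  } else {
    stats::predict(adapter$fitted, data = as.data.frame(x),
                   num.threads = 1)$predictions[, "1"]
  }
}

#' @export
print.case_classifier <- function(x, ...) {
  cat(sprintf("case_classifier [%s]: %s\n", x$family,
              if (is.null(x$fitted)) "unfitted" else
                sprintf("fitted on %d features, horizon %d",
                        length(x$feature_names), x$horizon)))
  invisible(x)
}
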