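#' Temporal-stratified k-fold assignment (TSK-fold)
#'
#' Cross-validation folds for the augmented dataset that preserve both the
#' temporal structure and the class balance: rows are stratified jointly on
#' the period \code{tau} (optionally grouped into wider intervals) and the
#' label \code{y}, shuffled within each stratum, and dealt round-robin to
#' the \code{k} folds, so within every (period, label) stratum the fold
#' sizes differ by at most one. Plain stratified k-fold ignores \code{tau}
#' and can leave individual folds with over- or under-represented periods.
#'
#' By default rows are assigned independently, reproducing the row-level
#' split the method was introduced with — note that a subject's replicates
#' can then appear in both training and test folds. \code{grouped = TRUE}
#' removes that leakage path by assigning all rows of a subject to one fold,
#' stratifying subjects on (completed periods, event indicator).
#'
#' @param augmented a \code{case_augmented} data frame.
#' @param k number of folds (>= 2).
#' @param seed integer seed; identical seed gives identical assignment.
#' @param repeats number of independent repetitions (default 1).
#' @param grouped logical; subject-level assignment (default \code{FALSE}).
#' @param interval_width width of the time intervals used as temporal strata
#'   (default 1, i.e. each period is its own stratum); widen for sparse-event
#'   settings.
#' @return An object of class \code{"tsk_fold"}: integer matrix of fold
#'   indices, one row per augmented row, one column per repeat, with
#'   attributes \code{k}, \code{grouped}, \code{seed}.
#' @export
tsk_fold <- function(augmented, k, seed = 1L, repeats = 1L, grouped = FALSE,
                     interval_width = 1L) {
  stopifnot(inherits(augmented, "case_augmented"))
  if (k < 2) stop("k must be at least 2")
  k <- as.integer(k)
  n <- nrow(augmented)
  interval <- (augmented$period - 1L) %/% as.integer(interval_width)

  assign_strata <- function(strata, rng_seed) {
    out <- integer(length(strata))
    set.seed(rng_seed)
    for (s in split(seq_along(strata), strata)) {
      if (length(s) < k) {
        warning(sprintf("stratum with %d row(s) is smaller than k = %d; spread over a subset of folds",
                        length(s), k), call. = FALSE)
      }
      sh <- s[sample.int(length(s))]
      out[sh] <- rep_len(sample.int(k), length(sh))
    }
    out
  }

  assignment <- matrix(NA_integer_, nrow = n, ncol = repeats)
  for (r in seq_len(repeats)) {
    rng_seed <- as.integer(seed) + (r - 1L) * 1000L
    if (grouped) {
      # stratify subjects by (completed periods at interval resolution, event)
      ids <- unique(augmented$source_id)
      n_pos <- tapply(augmented$label, augmented$source_id, sum)   # = min(floor(t), P)
      any_neg <- tapply(augmented$label == 0, augmented$source_id, any)
      strata <- paste((n_pos[ids] - 1L) %/% as.integer(interval_width),
                      ifelse(any_neg[ids], "event", "allpos"))
      fold_of_id <- stats::setNames(assign_strata(strata, rng_seed), ids)
      assignment[, r] <- fold_of_id[augmented$source_id]
    } else {
      strata <- paste(interval, augmented$label)
      assignment[, r] <- assign_strata(strata, rng_seed)
    }
  }
  colnames(assignment) <- paste0("repeat_", seq_len(repeats))
  structure(assignment, k = k, grouped = grouped, seed = as.integer(seed),
            class = c("tsk_fold", "matrix", "array"))
}

#' Plain stratified k-fold (label only), for comparison
#'
#' The conventional stratified split that balances the label but ignores the
#' period structure; used as the baseline TSK-fold is compared against.
#'
#' @inheritParams tsk_fold
#' @return Integer matrix as in \code{\link{tsk_fold}}.
#' @export
stratified_fold <- function(augmented, k, seed = 1L, repeats = 1L) {
  stopifnot(inherits(augmented, "case_augmented"))
  k <- as.integer(k)
  n <- nrow(augmented)
  assignment <- matrix(NA_integer_, nrow = n, ncol = repeats)
  for (r in seq_len(repeats)) {
    set.seed(as.integer(seed) + (r - 1L) * 1000L)
    for (s in split(seq_len(n), augmented$label)) {
      sh <- s[sample.int(length(s))]
      assignment[sh, r] <- rep_len(sample.int(k), length(sh))
    }
  }
  colnames(assignment) <- paste0("repeat_", seq_len(repeats))
  structure(assignment, k = k, grouped = FALSE, seed = as.integer(seed),
            class = c("tsk_fold", "matrix", "array"))
}

#' Per-fold, per-period positive-class ratios
#'
#' For each fold of an assignment, the fraction of positive rows at each
#' period; \code{NaN} where a fold contains no rows for a period. The
#' dispersion of these ratios across folds at a fixed period measures how
#' well the split preserves the temporal class structure.
#'
#' @param augmented the \code{case_augmented} data the assignment was made on.
#' @param assignment a \code{\link{tsk_fold}} assignment.
#' @param rep_index which repeat to profile (default 1).
#' @return Numeric matrix \code{k x P} of positive ratios.
#' @export
fold_ratio_profile <- function(augmented, assignment, rep_index = 1L) {
  k <- attr(assignment, "k")
  P <- attr(augmented, "horizon")
  fold <- assignment[, rep_index]
  prof <- matrix(NaN, nrow = k, ncol = P,
                 dimnames = list(paste0("fold_", seq_len(k)),
                                 paste0("tau_", seq_len(P))))
  pos <- tapply(augmented$label, list(fold, augmented$period), mean)
  prof[as.integer(rownames(pos)), as.integer(colnames(pos))] <- pos
  prof
}

#' Write a fold assignment as CSV
#'
#' Columns \code{row_index,repeat,fold}.
#' @param assignment a \code{tsk_fold} assignment.
#' @param path file path.
#' @export
write_folds_csv <- function(assignment, path) {
  reps <- ncol(assignment)
  long <- data.frame(row_index = rep(seq_len(nrow(assignment)), times = reps),
                     rep = rep(seq_len(reps), each = nrow(assignment)),
                     fold = as.vector(assignment))
  names(long)[2] <- "repeat"
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
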