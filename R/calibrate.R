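#' Fit an adjusted Bayesian binning-in-quantiles (ABBQ) calibration map
#'
#' Sorts raw classifier scores, splits them into \code{bins} quantile bins of
#' (roughly) equal occupancy, and records each bin's empirical survival
#' probability \code{n_survive / n} together with the observed score range of
#' the bin. At prediction time (\code{\link{predict.abbq}}) a raw score
#' falling in bin \code{m} maps to
#' \deqn{\hat p = \hat p_{emp,m} + \frac{1}{M}\,
#'       \frac{p - \min_m}{\max_m - \min_m},}
#' the bin's empirical probability plus an intra-bin variability term that
#' preserves the within-bin ranking of raw scores, clipped to \code{[0, 1]}.
#'
#' Ties in scores are assigned to bins by stable sort order, so bin sizes can
#' deviate from exact equality when the score distribution has atoms.
#'
#' @param scores numeric vector of raw classifier scores in \code{[0, 1]}.
#' @param labels binary vector (1 = survived) of the same length.
#' @param bins number of quantile bins \code{M} (>= 1).
#' @param centered logical; if \code{TRUE}, subtract \code{0.5/M} so the
#'   intra-bin term is mean-zero instead of purely additive. Off by default:
#'   the additive form is the canonical one.
#' @return An object of class \code{"abbq"}: list with \code{bins} (M),
#'   \code{table} (per-bin \code{score_min}, \code{score_max}, \code{n},
#'   \code{n_survive}, \code{p_emp}), \code{breaks} (M+1 score quantiles)
#'   and \code{centered}.
#' @examples
#' set.seed(1)
#' s <- runif(200); y <- rbinom(200, 1, s)
#' m <- fit_abbq(s, y, bins = 10)
#' predict(m, c(0.1, 0.5, 0.9))
#' @export
fit_abbq <- function(scores, labels, bins, centered = FALSE) {
  stopifnot(length(scores) == length(labels))
  if (length(bins) != 1L || bins < 1 || bins != floor(bins)) {
    stop("bins must be a single integer >= 1")
  }
  bins <- as.integer(bins)
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1)) {
    stop("scores must be finite and within [0, 1]")
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  n <- length(scores)
  if (n < bins) {
    stop(sprintf("%d observations cannot fill %d bins; use a smaller M", n, bins))
  }
  ord <- order(scores)  # stable: ties keep input order
  s <- scores[ord]
  y <- labels[ord]
  # deal sorted scores into M contiguous chunks whose sizes differ by <= 1
  sizes <- rep.int(n %/% bins, bins)
  extra <- n %% bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin_of <- rep.int(seq_len(bins), sizes)
  tab <- data.frame(
    bin = seq_len(bins),
    score_min = tapply(s, bin_of, min),
    score_max = tapply(s, bin_of, max),
    n = as.integer(tapply(y, bin_of, length)),
    n_survive = as.integer(tapply(y, bin_of, sum))
  )
  tab$p_emp <- tab$n_survive / tab$n
  breaks <- c(tab$score_min[1L], tab$score_max)
  structure(list(bins = bins, table = tab, breaks = breaks,
                 centered = isTRUE(centered)),
            class = "abbq")
}

#' Apply an ABBQ calibration map to raw scores
#'
#' Scores outside the fitted range are clamped into the first/last bin. A
#' degenerate bin (zero score spread) uses 0.5 as the normalized intra-bin
#' position. Output is always in \code{[0, 1]}.
#'
#' @param object an \code{"abbq"} map from \code{\link{fit_abbq}}.
#' @param scores numeric vector of raw scores.
#' @param ... unused.
#' @return Numeric vector of calibrated survival probabilities.
#' @export
predict.abbq <- function(object, scores, ...) {
  tab <- object$table
  M <- object$bins
  # locate bin by upper score boundary; clamp out-of-range scores
  bin <- findInterval(scores, tab$score_max, left.open = TRUE) + 1L
  bin[bin > M] <- M
  bin[bin < 1L] <- 1L
  lo <- tab$score_min[bin]
  hi <- tab$score_max[bin]
  span <- hi - lo
  frac <- ifelse(span > 0, (pmin(pmax(scores, lo), hi) - lo) / span, 0.5)
  adj <- if (object$centered) (frac - 0.5) / M else frac / M
  pmin(pmax(tab$p_emp[bin] + adj, 0), 1)
}

#' @export
print.abbq <- function(x, ...) {
  cat(sprintf("ABBQ calibration map: %d quantile bins over scores [%.4f, %.4f]%s\n",
              x$bins, x$table$score_min[1L], x$table$score_max[x$bins],
              if (x$centered) " (centered)" else ""))
  invisible(x)
}

#' Choose the ABBQ bin count by validation calibration error
#'
#' Fits an ABBQ map on the training scores for each candidate bin count and
#' returns the candidate whose calibrated predictions minimize expected
#' calibration error (\code{\link{ece}}) on a disjoint validation split.
#' Ties are broken toward the smaller bin count. Candidates larger than the
#' training-set size are skipped.
#'
#' @param scores_train,labels_train scores and labels used to fit each map.
#' @param scores_val,labels_val disjoint validation scores and labels.
#' @param candidates integer vector of bin counts to try (default 5..100 by 5).
#' @param ece_bins bins for the ECE evaluation (default 10).
#' @return List with \code{best} (chosen M), \code{ece} (named vector of
#'   validation ECE per candidate) and \code{map} (the refitted map at
#'   \code{best}).
#' @export
tune_bin_count <- function(scores_train, labels_train, scores_val, labels_val,
                           candidates = seq(5L, 100L, by = 5L),
                           ece_bins = 10L) {
  candidates <- sort(unique(as.integer(candidates)))
  candidates <- candidates[candidates >= 1 & candidates <= length(scores_train)]
  if (length(candidates) == 0L) stop("no feasible bin-count candidate")
  errs <- vapply(candidates, function(m) {
    map <- fit_abbq(scores_train, labels_train, bins = m)
    ece(predict(map, scores_val), labels_val, bins = ece_bins)
  }, numeric(1))
  names(errs) <- candidates
  best <- candidates[which.min(errs)]  # which.min takes the first == smallest M
  list(best = best, ece = errs,
       map = fit_abbq(scores_train, labels_train, bins = best))
}

#' Serialize / restore an ABBQ map as JSON
#'
#' Round-trips the bin table so a fitted map can be reused at prediction
#' time without refitting.
#'
#' @param object an \code{"abbq"} map.
#' @param path file path for the JSON document.
#' @export
abbq_to_json <- function(object, path) {
  jsonlite::write_json(
    list(bins = object$bins, centered = object$centered,
         breaks = object$breaks, table = object$table),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname abbq_to_json
#' @export
abbq_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- as.data.frame(doc$table)
  tab$n <- as.integer(tab$n)
  tab$n_survive <- as.integer(tab$n_survive)
  structure(list(bins = as.integer(doc$bins), table = tab,
                 breaks = as.numeric(doc$breaks),
                 centered = isTRUE(doc$centered)),
            class = "abbq")
}
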