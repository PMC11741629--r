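#' Construct a survival dataset
#'
#' A \code{survival_data} object is a data frame with one row per subject:
#' a unique identifier, an observed time (in periods, e.g. years), a binary
#' event indicator (1 = event observed at \code{time}, 0 = censored at
#' \code{time}) and an arbitrary set of covariate columns. It is the input
#' to the person-period augmentation operator (\code{\link{case_augment}})
#' and to every downstream stage.
#'
#' @param df data frame containing at least columns \code{id}, \code{time}
#'   and \code{event}; all remaining columns are treated as covariates.
#' @param id,time,event names of the identifier, time and event columns.
#' @return A data frame of class \code{"survival_data"} with columns
#'   \code{id}, \code{time}, \code{event}, then the covariates. Feature
#'   names are stored in \code{attr(x, "features")}.
#' @examples
#' d <- as_survival_data(data.frame(id = c("a", "b"), time = c(6, 6),
#'                                  event = c(0, 1), age = c(50, 61)))
#' attr(d, "features")
#' @export
as_survival_data <- function(df, id = "id", time = "time", event = "event") {
  df <- as.data.frame(df)
  need <- c(id, time, event)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  feats <- setdiff(names(df), need)
  out <- data.frame(id = as.character(df[[id]]),
                    time = as.numeric(df[[time]]),
                    event = df[[event]],
                    df[, feats, drop = FALSE],
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("id", "time", "event", feats)
  validate_survival_data(out, features = feats)
  structure(out, features = feats, class = c("survival_data", "data.frame"))
}

validate_survival_data <- function(df, features) {
  bad_t <- which(!is.finite(df$time) | df$time < 0)
  if (length(bad_t) > 0L) {
    stop("negative or non-finite time for record(s): ",
         paste(df$id[utils::head(bad_t, 5L)], collapse = ", "))
  }
  bad_e <- which(!(df$event %in% c(0, 1)))
  if (length(bad_e) > 0L) {
    stop("event indicator must be 0 or 1; offending record(s): ",
         paste(df$id[utils::head(bad_e, 5L)], collapse = ", "))
  }
  if (anyDuplicated(df$id)) {
    stop("subject ids are not unique: ",
         paste(unique(df$id[duplicated(df$id)])[1:min(5, sum(duplicated(df$id)))],
               collapse = ", "))
  }
  invisible(df)
}

#' @export
print.survival_data <- function(x, ...) {
  cat(sprintf("survival_data: %d subjects, %d events (%.1f%%), %d covariates\n",
              nrow(x), sum(x$event), if (nrow(x)) 100 * mean(x$event) else 0,
              length(attr(x, "features"))))
  NextMethod()
}

#' Completed periods of an observed time
#'
#' Reduces a (possibly fractional) observed time to the number of whole
#' periods verifiably survived: a subject censored at 6.4 years has survived
#' 6 complete periods.
#'
#' @param t numeric vector of non-negative times.
#' @return Integer vector \code{floor(t)}.
#' @export
floor_periods <- function(t) as.integer(floor(t))

#' Read / write survival datasets as CSV
#'
#' The on-disk format is one header row, columns \code{id,time,event}
#' followed by covariates.
#'
#' @param path file path.
#' @return \code{read_survival_csv} returns a \code{survival_data} object.
#' @export
read_survival_csv <- function(path) {
  as_survival_data(utils::read.csv(path, check.names = FALSE,
                                   stringsAsFactors = FALSE))
}

#' @rdname read_survival_csv
#' @param data a \code{survival_data} object.
#' @export
write_survival_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}
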