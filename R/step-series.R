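#' Construct and validate a minute-epoch step series
#'
#' A step series is a plain `data.frame` holding one participant's
#' minute-by-minute step counts: columns `participant_id`, `day` (integer day
#' index), `minute` (minute of day, 0--1439) and `steps` (non-negative integer
#' steps recorded in that 60-s epoch). Rows must be in strictly increasing
#' `(day, minute)` order with no duplicates. Recording need not be contiguous;
#' every function in the package treats a jump of more than one minute between
#' consecutive rows as a recording boundary that intervals and bouts cannot
#' span.
#'
#' @param day integer vector of day indices.
#' @param minute integer vector of minutes of day (0--1439).
#' @param steps non-negative integer vector of step counts.
#' @param participant_id scalar identifier, recycled to all rows.
#' @return A validated step-series `data.frame`.
#' @examples
#' step_series(day = 1, minute = 0:5, steps = c(0, 0, 12, 20, 1, 0))
#' @export
step_series <- function(day, minute, steps, participant_id = "P1") {
  df <- data.frame(
    participant_id = as.character(participant_id),
    day = as.integer(day),
    minute = as.integer(minute),
    steps = steps,
    stringsAsFactors = FALSE
  )
  validate_step_series(df)
  df$steps <- as.integer(df$steps)
  df
}

#' Validate a step-series data frame
#'
#' Checks the invariants described in [step_series()]; called internally by all
#' processing functions and exported so coerced external data can be checked.
#'
#' @param series a step-series `data.frame`.
#' @return The series, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_step_series <- function(series) {
  if (!is.data.frame(series) || nrow(series) == 0L) {
    stop("step series must be a non-empty data.frame")
  }
  need <- c("day", "minute", "steps")
  miss <- setdiff(need, names(series))
  if (length(miss)) {
    stop("step series is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyNA(series$day) || anyNA(series$minute) || anyNA(series$steps)) {
    stop("step series contains missing values")
  }
  if (any(series$minute < 0L | series$minute > 1439L)) {
    stop("minute of day must be in 0..1439")
  }
  if (any(series$steps < 0) || any(series$steps != floor(series$steps))) {
    stop("steps must be non-negative integers")
  }
  t_abs <- as.numeric(series$day) * 1440 + as.numeric(series$minute)
  if (any(diff(t_abs) <= 0)) {
    stop("step series must be in strictly increasing (day, minute) order with no duplicate minutes")
  }
  invisible(series)
}

# Absolute minute index used to detect recording boundaries.
abs_minute <- function(series) {
  as.numeric(series$day) * 1440 + as.numeric(series$minute)
}

#' Read / write minute-epoch step-count CSV files
#'
#' The on-disk format has columns `participant_id`, `day`, `minute_of_day`,
#' `steps` (one row per recorded minute, one or several participants per
#' file). `read_step_series()` also accepts a `minute` column in place of
#' `minute_of_day`, so exports from other tooling can be coerced by renaming
#' columns only.
#'
#' @param path file path.
#' @return `read_step_series()` returns a step-series `data.frame` (possibly
#'   covering several participants); `write_step_series()` returns `path`
#'   invisibly.
#' @export
read_step_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"minute" %in% names(df) && "minute_of_day" %in% names(df)) {
    names(df)[names(df) == "minute_of_day"] <- "minute"
  }
  if (!"participant_id" %in% names(df)) df$participant_id <- "P1"
  df <- df[c("participant_id", "day", "minute", "steps")]
  df$day <- as.integer(df$day)
  df$minute <- as.integer(df$minute)
  df$steps <- as.integer(df$steps)
  for (p in split(df, df$participant_id)) validate_step_series(p)
  df
}

#' @param series a step-series `data.frame`.
#' @rdname read_step_series
#' @export
write_step_series <- function(series, path) {
  out <- series[c("participant_id", "day", "minute", "steps")]
  names(out)[names(out) == "minute"] <- "minute_of_day"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
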