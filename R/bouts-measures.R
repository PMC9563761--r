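#' Extract walking and sedentary bouts
#'
#' A bout is a maximal run of consecutive same-label wear minutes. Non-wear
#' minutes and breaks in recording terminate bouts; a bout that spans midnight
#' is attributed to the day on which it starts. Walking bouts carry their step
#' total and cadence (steps per minute); sedentary bouts carry a zero step
#' total (any spurious single steps on sedentary minutes are not bout steps).
#'
#' @param series a step series.
#' @param labels per-minute labels in `{"nonwear", "active", "sedentary"}`.
#' @return A `data.frame` with columns `kind` (`"walking"` or `"sedentary"`),
#'   `day`, `start_minute`, `duration_minutes`, `total_steps`, `cadence`
#'   (`NA` for sedentary bouts). Zero rows when there is no wear time.
#' @examples
#' s <- step_series(day = 1, minute = 0:5, steps = c(10, 20, 30, 0, 0, 5))
#' extract_bouts(s, classify_minutes(s, nonwear_params(window_minutes = 10)))
#' @export
extract_bouts <- function(series, labels) {
  validate_step_series(series)
  n <- nrow(series)
  if (length(labels) != n) stop("labels are misaligned with the series")
  brk <- c(TRUE, diff(abs_minute(series)) != 1 | labels[-1L] != labels[-n])
  run <- cumsum(brk)
  first <- which(brk)
  kind_lab <- labels[first]
  keep <- kind_lab != "nonwear"
  dur <- tabulate(run, nbins = max(run))
  steps_by_run <- as.vector(rowsum(as.numeric(series$steps), run))
  out <- data.frame(
    kind = ifelse(kind_lab == "active", "walking", "sedentary")[keep],
    day = series$day[first][keep],
    start_minute = series$minute[first][keep],
    duration_minutes = dur[keep],
    total_steps = ifelse(kind_lab[keep] == "active", steps_by_run[keep], 0),
    stringsAsFactors = FALSE
  )
  out$cadence <- ifelse(out$kind == "walking",
                        out$total_steps / out$duration_minutes, NA_real_)
  out
}

# Restrict a series and its labels to the valid days.
filter_valid_days <- function(series, labels, valid_days) {
  days <- if (inherits(valid_days, "valid_day_set")) valid_days$valid_days else valid_days
  if (length(days) == 0L) {
    stop("no valid recording days: insufficient data to compute activity measures")
  }
  keep <- series$day %in% days
  list(series = series[keep, , drop = FALSE], labels = labels[keep],
       n_days = length(days))
}

#' Activity volume and frequency measures
#'
#' Five per-day averages over the valid recording period: steps per day (all
#' steps on wear minutes), time walking per day (active minutes), and the
#' number of short (`< short_bout_steps` total steps), long
#' (`>= long_bout_steps`), and all walking bouts per day. Bouts of
#' intermediate step totals count toward the overall bout rate but toward
#' neither subtype.
#'
#' @param series a step series.
#' @param labels per-minute labels.
#' @param valid_days a `valid_day_set` or integer vector of valid days.
#' @param short_bout_steps exclusive upper step total for a short bout
#'   (default 40).
#' @param long_bout_steps inclusive lower step total for a long bout
#'   (default 300).
#' @return Named list with `avg_steps_per_day`, `avg_time_walking_per_day`,
#'   `avg_short_bouts_per_day`, `avg_long_bouts_per_day`, `avg_bouts_per_day`.
#' @export
compute_volume_frequency <- function(series, labels, valid_days,
                                     short_bout_steps = 40, long_bout_steps = 300) {
  f <- filter_valid_days(series, labels, valid_days)
  bouts <- extract_bouts(f$series, f$labels)
  walking <- bouts[bouts$kind == "walking", , drop = FALSE]
  list(
    avg_steps_per_day = sum(f$series$steps[f$labels != "nonwear"]) / f$n_days,
    avg_time_walking_per_day = sum(f$labels == "active") / f$n_days,
    avg_short_bouts_per_day = sum(walking$total_steps < short_bout_steps) / f$n_days,
    avg_long_bouts_per_day = sum(walking$total_steps >= long_bout_steps) / f$n_days,
    avg_bouts_per_day = nrow(walking) / f$n_days
  )
}

#' Activity intensity measures
#'
#' `peak30` is the mean over valid days of the average of each day's 30
#' highest per-minute step counts among wear minutes; days with fewer than 30
#' wear minutes are padded with zeros so the statistic stays defined.
#' `avg_bout_cadence` is the mean of per-bout cadences (bout steps / bout
#' minutes) pooled over all walking bouts of the valid period; it is `NA` when
#' there are no walking bouts.
#'
#' @inheritParams compute_volume_frequency
#' @param peak_minutes number of top minutes averaged per day (default 30).
#' @return Named list with `peak30` and `avg_bout_cadence`.
#' @export
compute_intensity <- function(series, labels, valid_days, peak_minutes = 30L) {
  f <- filter_valid_days(series, labels, valid_days)
  wear <- f$labels != "nonwear"
  day_of <- f$series$day[wear]
  wear_steps <- f$series$steps[wear]
  days <- if (inherits(valid_days, "valid_day_set")) valid_days$valid_days else valid_days
  peak_by_day <- vapply(days, function(d) {
    s <- wear_steps[day_of == d]
    if (length(s) == 0L) return(0)
    sum(sort(s, decreasing = TRUE)[seq_len(min(peak_minutes, length(s)))]) / peak_minutes
  }, numeric(1))
  bouts <- extract_bouts(f$series, f$labels)
  cad <- bouts$cadence[bouts$kind == "walking"]
  list(
    peak30 = mean(peak_by_day),
    avg_bout_cadence = if (length(cad)) mean(cad) else NA_real_
  )
}

#' Sedentary-behavior measures
#'
#' `percent_sedentary_time` is sedentary minutes over total wear minutes of
#' the valid period, as a percentage. `avg_long_sedentary_bouts_per_day`
#' counts sedentary bouts of at least `long_sed_minutes` (default 30 min) per
#' valid day. `fragmentation_index` is the number of sedentary bouts of at
#' least `frag_min_minutes` (default 5 min) divided by total sedentary
#' minutes; higher values indicate more interrupted sedentary behavior. It is
#' `NA` when there are no sedentary minutes.
#'
#' @inheritParams compute_volume_frequency
#' @param long_sed_minutes minimum duration of a long sedentary bout
#'   (default 30).
#' @param frag_min_minutes minimum bout duration counted in the fragmentation
#'   numerator (default 5).
#' @return Named list with `percent_sedentary_time`,
#'   `avg_long_sedentary_bouts_per_day`, `fragmentation_index`.
#' @export
compute_sedentary <- function(series, labels, valid_days,
                              long_sed_minutes = 30L, frag_min_minutes = 5L) {
  f <- filter_valid_days(series, labels, valid_days)
  wear_min <- sum(f$labels != "nonwear")
  if (wear_min == 0L) stop("no wear minutes on the valid days")
  sed_min <- sum(f$labels == "sedentary")
  bouts <- extract_bouts(f$series, f$labels)
  sed <- bouts[bouts$kind == "sedentary", , drop = FALSE]
  list(
    percent_sedentary_time = 100 * sed_min / wear_min,
    avg_long_sedentary_bouts_per_day =
      sum(sed$duration_minutes >= long_sed_minutes) / f$n_days,
    fragmentation_index =
      if (sed_min == 0L) NA_real_ else sum(sed$duration_minutes >= frag_min_minutes) / sed_min
  )
}

#' The ten activity measures
#'
#' Computes all ten per-participant activity measures over the valid recording
#' days, grouped by domain: activity volume (`avg_steps_per_day`,
#' `avg_time_walking_per_day`), activity frequency (`avg_short_bouts_per_day`,
#' `avg_long_bouts_per_day`, `avg_bouts_per_day`), activity intensity
#' (`peak30`, `avg_bout_cadence`), and sedentary behavior
#' (`percent_sedentary_time`, `avg_long_sedentary_bouts_per_day`,
#' `fragmentation_index`).
#'
#' @inheritParams compute_volume_frequency
#' @inheritParams compute_intensity
#' @inheritParams compute_sedentary
#' @return A one-row `data.frame` with the ten measures plus `n_valid_days`
#'   (and `participant_id` when present in `series`).
#' @export
activity_measures <- function(series, labels, valid_days,
                              short_bout_steps = 40, long_bout_steps = 300,
                              peak_minutes = 30L, long_sed_minutes = 30L,
                              frag_min_minutes = 5L) {
  vf <- compute_volume_frequency(series, labels, valid_days,
                                 short_bout_steps, long_bout_steps)
  it <- compute_intensity(series, labels, valid_days, peak_minutes)
  sb <- compute_sedentary(series, labels, valid_days,
                          long_sed_minutes, frag_min_minutes)
  nd <- if (inherits(valid_days, "valid_day_set")) valid_days$n_valid else length(valid_days)
  out <- data.frame(c(vf, it, sb), n_valid_days = nd)
  if ("participant_id" %in% names(series)) {
    out <- cbind(participant_id = series$participant_id[1L], out,
                 stringsAsFactors = FALSE)
  }
  out
}

#' Names of the ten activity measures
#'
#' @return Character vector of the ten measure column names in domain order.
#' @export
measure_names <- function() {
  c("avg_steps_per_day", "avg_time_walking_per_day",
    "avg_short_bouts_per_day", "avg_long_bouts_per_day", "avg_bouts_per_day",
    "peak30", "avg_bout_cadence",
    "percent_sedentary_time", "avg_long_sedentary_bouts_per_day",
    "fragmentation_index")
}
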