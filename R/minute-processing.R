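#' Non-wear detection parameters
#'
#' The device is judged not worn over any interval of at least
#' `window_minutes` consecutive minutes whose step counts are all zero, except
#' that up to `spurious_allowance` minutes of at most `spurious_max_steps`
#' steps each are tolerated inside the interval. Interval endpoints must be
#' zero-step minutes, so low-step minutes at the edge of a gap are never
#' absorbed into it. Defaults correspond to a 4-h window with two spurious
#' minutes of up to 2 steps.
#'
#' @param window_minutes minimum interval length in minutes (default 240).
#' @param spurious_allowance tolerated non-zero minutes per interval (default 2).
#' @param spurious_max_steps maximum steps in a tolerated minute (default 2).
#' @return A list of class `nonwear_params`.
#' @export
nonwear_params <- function(window_minutes = 240L, spurious_allowance = 2L,
                           spurious_max_steps = 2L) {
  window_minutes <- as.integer(window_minutes)
  spurious_allowance <- as.integer(spurious_allowance)
  spurious_max_steps <- as.integer(spurious_max_steps)
  if (is.na(window_minutes) || window_minutes < 1L) stop("window_minutes must be >= 1")
  if (is.na(spurious_allowance) || spurious_allowance < 0L) stop("spurious_allowance must be >= 0")
  if (is.na(spurious_max_steps) || spurious_max_steps < 0L) stop("spurious_max_steps must be >= 0")
  structure(
    list(window_minutes = window_minutes,
         spurious_allowance = spurious_allowance,
         spurious_max_steps = spurious_max_steps),
    class = "nonwear_params"
  )
}

#' Detect non-wear minutes in a step series
#'
#' Labels each minute `"nonwear"` or `"wear"`. A minute is non-wear when it is
#' covered by at least one qualifying interval: a stretch of at least
#' `window_minutes` consecutive recorded minutes, starting and ending on a
#' zero-step minute, in which every minute has zero steps except at most
#' `spurious_allowance` minutes of `1..spurious_max_steps` steps each.
#' Overlapping qualifying intervals merge into maximal non-wear runs; the
#' spurious allowance is always evaluated over a whole candidate interval, so
#' a longer interval never earns a larger allowance. Intervals may span
#' midnight but never a break in recording (a jump of more than one minute
#' between consecutive rows).
#'
#' @param series a step series, see [step_series()].
#' @param params a [nonwear_params()] object.
#' @return Character vector of per-minute labels, `"nonwear"` or `"wear"`,
#'   aligned with the rows of `series`.
#' @examples
#' s <- step_series(day = 1, minute = 0:299,
#'                  steps = c(10, rep(0, 297), 5, 8))
#' table(detect_nonwear(s))
#' @export
detect_nonwear <- function(series, params = nonwear_params()) {
  validate_step_series(series)
  stopifnot(inherits(params, "nonwear_params"))
  steps <- as.integer(series$steps)
  n <- length(steps)
  seg <- cumsum(c(1L, as.integer(diff(abs_minute(series)) != 1)))
  nonwear <- logical(n)
  for (idx in split(seq_len(n), seg)) {
    nonwear[idx] <- nonwear_flags(steps[idx], params)
  }
  ifelse(nonwear, "nonwear", "wear")
}

# Core non-wear scan over one contiguous stretch of minutes.
# Within each run of minutes with steps <= spurious_max_steps, the furthest
# qualifying endpoint e(s) for every zero-step start s is found with running
# spurious counts; e(s) is non-decreasing in s, so the union of all
# qualifying [s, e(s)] is computed with cumulative coverage counts.
nonwear_flags <- function(steps, params) {
  w <- params$window_minutes
  allow <- params$spurious_allowance
  mx <- params$spurious_max_steps
  n <- length(steps)
  out <- logical(n)
  if (n < w) return(out)
  eligible <- steps <= mx
  r <- rle(eligible)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  for (k in which(r$values & r$lengths >= w)) {
    a <- run_start[k]
    b <- run_end[k]
    s <- steps[a:b]
    m <- length(s)
    cs <- cumsum(as.integer(s > 0L))       # spurious minutes so far
    zero <- s == 0L
    lastzero <- cummax(ifelse(zero, seq_len(m), 0L))
    st <- which(zero)                       # candidate interval starts
    if (!length(st)) next
    budget <- c(0L, cs)[st] + allow         # cs[st - 1] + allowance
    e_lim <- findInterval(budget, cs)       # last index with cs <= budget
    e_max <- lastzero[pmin(pmax(e_lim, 1L), m)]
    ok <- (e_max - st + 1L) >= w
    if (!any(ok)) next
    ss <- st[ok]
    ee <- e_max[ok]
    covered_from <- cumsum(tabulate(ss, nbins = m))
    ended_before <- c(0L, cumsum(tabulate(ee, nbins = m)))[seq_len(m)]
    covered <- (covered_from - ended_before) > 0L
    out[(a:b)[covered]] <- TRUE
  }
  out
}

#' Classify wear minutes as active or sedentary
#'
#' A wear minute is active when it has at least 1 step, with the exception
#' that a minute with exactly 1 step flanked by zero-step minutes on both
#' sides is sedentary (a spurious single step). A missing neighbor -- the
#' start or end of recording, a break in recording, or an adjacent non-wear
#' minute -- counts as a zero-step neighbor, so an isolated single step at a
#' boundary is sedentary. Non-wear minutes are passed through unchanged.
#'
#' @param series a step series.
#' @param wear per-minute labels from [detect_nonwear()] (any label other than
#'   `"nonwear"` is treated as wear, so the function is idempotent on its own
#'   output).
#' @return Character vector of labels in `{"nonwear", "active", "sedentary"}`.
#' @examples
#' s <- step_series(day = 1, minute = 0:3, steps = c(10, 12, 0, 20))
#' classify_active_sedentary(s, rep("wear", 4))
#' @export
classify_active_sedentary <- function(series, wear) {
  validate_step_series(series)
  n <- nrow(series)
  if (length(wear) != n) {
    stop("wear labels are misaligned with the series (", length(wear),
         " labels for ", n, " minutes)")
  }
  steps <- as.integer(series$steps)
  nw <- wear == "nonwear"
  contig <- diff(abs_minute(series)) == 1

  prev_zero <- rep(TRUE, n)                 # missing neighbor counts as zero
  i <- which(c(FALSE, contig))
  prev_zero[i] <- nw[i - 1L] | steps[i - 1L] == 0L
  next_zero <- rep(TRUE, n)
  j <- which(c(contig, FALSE))
  next_zero[j] <- nw[j + 1L] | steps[j + 1L] == 0L

  active <- !nw & (steps >= 2L | (steps == 1L & !(prev_zero & next_zero)))
  out <- ifelse(nw, "nonwear", ifelse(active, "active", "sedentary"))
  out
}

#' Full minute classification in one call
#'
#' Runs [detect_nonwear()] then [classify_active_sedentary()].
#'
#' @inheritParams detect_nonwear
#' @return Character vector of labels in `{"nonwear", "active", "sedentary"}`.
#' @export
classify_minutes <- function(series, params = nonwear_params()) {
  classify_active_sedentary(series, detect_nonwear(series, params))
}

#' Determine valid recording days
#'
#' A day is valid when its wear minutes (any label other than `"nonwear"`)
#' reach `min_wear_minutes`. When `exclude_edge_days` is `TRUE` the first and
#' last observed recording days are excluded regardless of wear time (the days
#' the device was issued and returned). Participants with fewer than
#' `min_days` valid days are flagged (`below_minimum`) rather than erroring,
#' so callers can exclude them.
#'
#' @param series a step series.
#' @param labels per-minute labels aligned to `series`.
#' @param min_wear_minutes wear-minute threshold for a valid day (default 600,
#'   i.e. 10 h).
#' @param exclude_edge_days drop the first and last observed days (default
#'   `TRUE`).
#' @param min_days minimum number of valid days expected (default 3).
#' @return A list of class `valid_day_set` with elements `valid_days`
#'   (sorted integer vector), `n_valid`, `below_minimum`, and the thresholds
#'   used.
#' @export
determine_valid_days <- function(series, labels, min_wear_minutes = 600L,
                                 exclude_edge_days = TRUE, min_days = 3L) {
  validate_step_series(series)
  if (length(labels) != nrow(series)) stop("labels are misaligned with the series")
  min_wear_minutes <- as.integer(min_wear_minutes)
  if (min_wear_minutes > 1440L) stop("min_wear_minutes cannot exceed 1440")
  wear_by_day <- tapply(labels != "nonwear", series$day, sum)
  days <- as.integer(names(wear_by_day))
  valid <- days[as.integer(wear_by_day) >= min_wear_minutes]
  if (exclude_edge_days) valid <- setdiff(valid, range(days))
  valid <- sort(valid)
  structure(
    list(valid_days = valid,
         n_valid = length(valid),
         below_minimum = length(valid) < min_days,
         min_wear_minutes = min_wear_minutes,
         exclude_edge_days = exclude_edge_days,
         min_days = as.integer(min_days)),
    class = "valid_day_set"
  )
}

#' @export
print.valid_day_set <- function(x, ...) {
  cat("Valid recording days:", x$n_valid,
      sprintf("(threshold %d wear min, edge days %s)\n",
              x$min_wear_minutes,
              if (x$exclude_edge_days) "excluded" else "included"))
  cat("  days:", paste(x$valid_days, collapse = ", "), "\n")
  if (x$below_minimum) {
    cat("  NOTE: below the", x$min_days, "valid-day minimum\n")
  }
  invisible(x)
}

#' Sweep non-wear window lengths
#'
#' Reclassifies the series at each candidate non-wear window and tabulates the
#' resulting minute totals, supporting a descriptive comparison of window
#' choices (for example 3 h through 6 h).
#'
#' @param series a step series.
#' @param windows integer vector of window lengths in minutes.
#' @param params base [nonwear_params()]; the window is replaced per sweep.
#' @return A `data.frame` with one row per window: `window_minutes`,
#'   `nonwear_minutes`, `sedentary_minutes`, `active_minutes`.
#' @export
sweep_nonwear_windows <- function(series, windows, params = nonwear_params()) {
  if (length(windows) == 0L) stop("windows must be non-empty")
  rows <- lapply(as.integer(windows), function(w) {
    p <- nonwear_params(w, params$spurious_allowance, params$spurious_max_steps)
    lab <- classify_minutes(series, p)
    data.frame(window_minutes = w,
               nonwear_minutes = sum(lab == "nonwear"),
               sedentary_minutes = sum(lab == "sedentary"),
               active_minutes = sum(lab == "active"))
  })
  do.call(rbind, rows)
}

#' Percent agreement between two minute labelings
#'
#' Share of minutes on which two aligned labelings agree, over the three-way
#' alphabet `{"nonwear", "active", "sedentary"}`, expressed as a percentage.
#' Used to compare algorithmic labels with a reference coding.
#'
#' @param labels,reference equal-length character vectors of labels.
#' @return A single percentage in `[0, 100]`.
#' @export
percent_agreement <- function(labels, reference) {
  if (length(labels) != length(reference)) {
    stop("labelings differ in length (", length(labels), " vs ",
         length(reference), ")")
  }
  if (length(labels) == 0L) stop("labelings are empty")
  100 * mean(labels == reference)
}
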