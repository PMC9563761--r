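#' Configure a synthetic minute-epoch recording
#'
#' Describes one participant's recording as a deterministic layout plus a
#' seed: `n_days` calendar days of 1440 minutes; a daily wake window of
#' `wake_minutes_per_day` minutes starting at `wake_start` (minutes outside it
#' are zero-step "sleep/off-body" time, 480 min per day by default, long
#' enough to be detected as non-wear); explicit non-wear gaps; walking bouts
#' of given start, duration and cadence; explicit spurious low-step minutes;
#' and a rate at which background sedentary minutes receive an isolated single
#' step. Within a day, gaps, bouts and spurious minutes must not overlap.
#'
#' @param n_days number of recording days.
#' @param wake_minutes_per_day length of the daily wake window (default 960).
#' @param wake_start minute of day at which the wake window opens (default
#'   480, i.e. 08:00, leaving a 480-min zero-step block at the start of each
#'   day).
#' @param nonwear_gaps list of `c(day, start_minute, length_minutes)` vectors.
#' @param walking_bouts list of `c(day, start_minute, duration_minutes,
#'   cadence_steps_per_min)` vectors.
#' @param spurious_minutes list of `c(day, minute, steps)` vectors with
#'   `steps <= 2`.
#' @param sedentary_one_rate probability that a background wake sedentary
#'   minute carries an isolated single step (default 0.04, about one per 25 min). These single
#'   steps are sedentary by the classification rule and keep long wake
#'   sedentary stretches from resembling non-wear.
#' @param participant_id identifier attached to the series.
#' @param seed integer seed; the same profile and seed always reproduce the
#'   same series.
#' @return A list of class `series_profile`.
#' @export
series_profile <- function(n_days, wake_minutes_per_day = 960L, wake_start = 480L,
                           nonwear_gaps = list(), walking_bouts = list(),
                           spurious_minutes = list(), sedentary_one_rate = 0.04,
                           participant_id = "P1", seed = NULL) {
  n_days <- as.integer(n_days)
  if (is.na(n_days) || n_days < 1L) stop("n_days must be a positive integer")
  wake_minutes_per_day <- as.integer(wake_minutes_per_day)
  wake_start <- as.integer(wake_start)
  if (wake_start < 0L || wake_start + wake_minutes_per_day > 1440L) {
    stop("wake window must fit within the day")
  }
  if (sedentary_one_rate < 0 || sedentary_one_rate >= 1) {
    stop("sedentary_one_rate must be in [0, 1)")
  }
  prof <- structure(
    list(n_days = n_days,
         wake_minutes_per_day = wake_minutes_per_day,
         wake_start = wake_start,
         nonwear_gaps = nonwear_gaps,
         walking_bouts = walking_bouts,
         spurious_minutes = spurious_minutes,
         sedentary_one_rate = sedentary_one_rate,
         participant_id = participant_id,
         seed = seed),
    class = "series_profile"
  )
  validate_series_profile(prof)
  prof
}

# Occupied-interval bookkeeping: each configured segment as (day, start, end).
profile_segments <- function(prof) {
  seg <- list()
  for (g in prof$nonwear_gaps) {
    if (length(g) != 3L) stop("each non-wear gap must be c(day, start_minute, length_minutes)")
    seg[[length(seg) + 1L]] <- c(g[1], g[2], g[2] + g[3] - 1, 0)
  }
  for (b in prof$walking_bouts) {
    if (length(b) != 4L) stop("each walking bout must be c(day, start_minute, duration_minutes, cadence)")
    if (b[4] <= 0) stop("bout cadence must be > 0")
    seg[[length(seg) + 1L]] <- c(b[1], b[2], b[2] + b[3] - 1, 1)
  }
  for (s in prof$spurious_minutes) {
    if (length(s) != 3L) stop("each spurious minute must be c(day, minute, steps)")
    if (s[3] < 0 || s[3] > 2) stop("spurious minutes must have 0..2 steps")
    seg[[length(seg) + 1L]] <- c(s[1], s[2], s[2], 2)
  }
  seg
}

validate_series_profile <- function(prof) {
  seg <- profile_segments(prof)
  for (s in seg) {
    if (s[1] < 1 || s[1] > prof$n_days) stop("configured segment lies outside the recording days")
    if (s[2] < 0 || s[3] > 1439) stop("configured segment lies outside the day")
  }
  if (length(seg) > 1L) {
    tab <- do.call(rbind, seg)
    for (d in unique(tab[, 1])) {
      iv <- tab[tab[, 1] == d, , drop = FALSE]
      iv <- iv[order(iv[, 2]), , drop = FALSE]
      if (nrow(iv) > 1L && any(iv[-1L, 2] <= iv[-nrow(iv), 3])) {
        stop("configured gaps, bouts and spurious minutes overlap on day ", d)
      }
    }
  }
  invisible(prof)
}

# Poisson draws truncated below at 1 (inverse-CDF), so every bout minute
# stays active by construction.
rpois_min1 <- function(n, lambda) {
  u <- runif(n, ppois(0, lambda), 1)
  pmax(1L, qpois(u, lambda))
}

#' Generate a synthetic step series with known minute labels
#'
#' Realizes a [series_profile()] into a minute-epoch step series of length
#' `n_days * 1440` together with the intended per-minute truth labels:
#' sleep/off-body edges and configured gaps are non-wear, walking-bout
#' minutes draw Poisson(cadence) steps truncated below at 1 and are active,
#' and remaining wake minutes are sedentary (zero steps, or an isolated
#' single step at the configured background rate). Truth labels for explicit
#' spurious minutes follow the active/sedentary classification rule, so for
#' unambiguous configurations re-deriving labels with [classify_minutes()]
#' reproduces the truth.
#'
#' @param profile a [series_profile()].
#' @return A list with `series` (step-series `data.frame`) and `truth`
#'   (character label vector aligned to it).
#' @examples
#' p <- series_profile(n_days = 2, walking_bouts = list(c(1, 600, 10, 80)),
#'                     seed = 1)
#' out <- generate_step_series(p)
#' sum(out$series$steps)
#' @export
generate_step_series <- function(profile) {
  stopifnot(inherits(profile, "series_profile"))
  validate_series_profile(profile)
  with_seed(profile$seed, {
    n <- profile$n_days * 1440L
    day <- rep(seq_len(profile$n_days), each = 1440L)
    minute <- rep(0:1439, times = profile$n_days)
    steps <- integer(n)
    truth <- rep("sedentary", n)
    at <- function(d, m) (d - 1L) * 1440L + m + 1L

    wake <- minute >= profile$wake_start &
      minute < profile$wake_start + profile$wake_minutes_per_day
    truth[!wake] <- "nonwear"

    for (g in profile$nonwear_gaps) {
      idx <- at(g[1], seq.int(g[2], length.out = g[3]))
      truth[idx] <- "nonwear"
    }
    for (b in profile$walking_bouts) {
      idx <- at(b[1], seq.int(b[2], length.out = b[3]))
      steps[idx] <- rpois_min1(length(idx), b[4])
      truth[idx] <- "active"
    }
    for (s in profile$spurious_minutes) {
      steps[at(s[1], s[2])] <- as.integer(s[3])
    }

    if (profile$sedentary_one_rate > 0) {
      bg <- which(wake & truth == "sedentary" & steps == 0L)
      sel <- bg[runif(length(bg)) < profile$sedentary_one_rate]
      if (length(sel) > 1L) sel <- sel[c(TRUE, diff(sel) > 1L)]
      # keep only minutes whose recorded neighbors are zero-step
      prev_ok <- sel == 1L | steps[pmax(sel - 1L, 1L)] == 0L
      next_ok <- sel == n | steps[pmin(sel + 1L, n)] == 0L
      sel <- sel[prev_ok & next_ok]
      steps[sel] <- 1L
    }

    # truth for explicit spurious minutes follows the classification rule
    for (s in profile$spurious_minutes) {
      i <- at(s[1], s[2])
      if (truth[i] == "nonwear") next
      p0 <- i == 1L || truth[i - 1L] == "nonwear" || steps[i - 1L] == 0L
      n0 <- i == n || truth[i + 1L] == "nonwear" || steps[i + 1L] == 0L
      truth[i] <- if (steps[i] >= 2L || (steps[i] == 1L && !(p0 && n0))) "active" else "sedentary"
    }

    series <- data.frame(participant_id = profile$participant_id,
                         day = day, minute = minute, steps = steps,
                         stringsAsFactors = FALSE)
    list(series = series, truth = truth)
  })
}
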