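# Independent reference implementations used as oracles.

# Brute-force non-wear checker: evaluates the rule for every candidate
# sub-interval directly from its definition (zero-step endpoints, no minute
# above spurious_max_steps, at most spurious_allowance non-zero minutes,
# length >= window) and marks the union of all qualifying intervals.
# Treats the whole vector as one contiguous recording.
brute_force_nonwear <- function(steps, params = nonwear_params()) {
  n <- length(steps)
  w <- params$window_minutes
  mx <- params$spurious_max_steps
  allow <- params$spurious_allowance
  out <- logical(n)
  if (n < w) return(out)
  cbad <- cumsum(steps > mx)
  cspur <- cumsum(steps > 0 & steps <= mx)
  j_all <- seq_len(n)
  for (i in which(steps == 0L)) {
    ok <- j_all >= i + w - 1L &
      steps == 0L &
      (cbad - c(0L, cbad)[i]) == 0L &
      (cspur - c(0L, cspur)[i]) <= allow
    if (any(ok)) out[i:max(j_all[ok])] <- TRUE
  }
  out
}

# Single-pass reference bout extractor over one contiguous labeled stretch.
naive_bouts <- function(steps, labels) {
  rows <- list()
  i <- 1L
  n <- length(steps)
  while (i <= n) {
    j <- i
    while (j < n && labels[j + 1L] == labels[i]) j <- j + 1L
    if (labels[i] != "nonwear") {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = if (labels[i] == "active") "walking" else "sedentary",
        duration_minutes = j - i + 1L,
        total_steps = if (labels[i] == "active") sum(steps[i:j]) else 0
      )
    }
    i <- j + 1L
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), duration_minutes = integer(),
               total_steps = numeric())
}

# Random step-count vector mixing long zero runs, activity bursts and
# scattered low-step minutes, to exercise non-wear/bout logic.
random_steps <- function(n) {
  steps <- integer(0)
  while (length(steps) < n) {
    kind <- sample(c("zeros", "long_zeros", "activity", "low"), 1,
                   prob = c(0.35, 0.2, 0.3, 0.15))
    len <- switch(kind,
      zeros = sample(5:120, 1),
      long_zeros = sample(200:420, 1),
      activity = sample(3:40, 1),
      low = sample(1:6, 1))
    seg <- switch(kind,
      zeros = integer(len),
      long_zeros = integer(len),
      activity = rpois(len, sample(c(5, 20, 60), 1)) + 1L,
      low = sample(0:2, len, replace = TRUE))
    steps <- c(steps, seg)
  }
  steps[seq_len(n)]
}

random_series <- function(n, id = "T1") {
  days <- ceiling(n / 1440)
  step_series(day = rep(seq_len(days), each = 1440)[seq_len(n)],
              minute = rep(0:1439, times = days)[seq_len(n)],
              steps = random_steps(n), participant_id = id)
}

# A fully deterministic-by-layout profile: bouts anchored at both wake edges
# and spaced so that no wake zero run can reach the non-wear window; the
# derived labels then equal the generator's truth exactly.
unambiguous_profile <- function(n_days = 3, seed = 1) {
  bouts <- list()
  for (d in seq_len(n_days)) {
    for (s in seq(480, 1320, by = 120)) {
      bouts[[length(bouts) + 1L]] <- c(d, s, 15, 40)
    }
    bouts[[length(bouts) + 1L]] <- c(d, 1425, 15, 40)  # ends at the wake edge
  }
  series_profile(n_days = n_days, wake_minutes_per_day = 960,
                 wake_start = 480, walking_bouts = bouts,
                 sedentary_one_rate = 0, seed = seed)
}
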