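#' Configure a synthetic study cohort
#'
#' Study conditions for a cohort of chronic-stroke participants: covariate
#' distributions, an activity-generation model, and a linear model for
#' systolic blood pressure (SBP) on standardized predictors with Gaussian
#' noise.
#'
#' Between-participant structure is generated from a latent mobility factor
#' plus independent channels, so the ten realized measures are correlated but
#' not collinear: mobility jointly scales the walking-bout rate, bout length
#' and bout cadence (`predictor_correlation` is the target correlation
#' between these core channels, and is also what ties the 6-Minute Walk Test
#' to real-world activity); separate, mostly independent channels control how
#' strongly walking clusters into a few activity periods per day (which
#' drives long sedentary bouts), the size of a participant's brisk-walking
#' cadence reserve (which drives peak30 beyond the average bout cadence), and
#' daily device-wear duration (which varies total wear time).
#'
#' Default activity parameters are chosen so the realized cohort resembles a
#' chronic-stroke sample wearing an ankle monitor: roughly 4000--4500 average
#' steps/day, about 82 percent sedentary time, SBP 128 (SD 16) mmHg, 6MWT
#' around 310 m.
#'
#' @param n_participants cohort size (default 276).
#' @param coef_map named numeric vector of standardized effect sizes on SBP;
#'   names must be activity measures (see [measure_names()]) or covariates
#'   (`age`, `gender`, `race_black`, `race_other`, `months_since_stroke`,
#'   `sixmwt_m`). The planted value is the standardized regression
#'   coefficient when SBP variance matches `sbp_sd`.
#' @param noise_sd residual SD of SBP in mmHg; `NULL` (default) calibrates it
#'   so the total SBP SD is approximately `sbp_sd`.
#' @param sbp_mean,sbp_sd location and scale of SBP in mmHg (defaults 128.13
#'   and 16.26).
#' @param predictor_correlation correlation between the core latent activity
#'   channels, in `[0, 1)` (default 0.4).
#' @param n_days recording days per participant (default 9; with first/last
#'   days excluded this yields 7 countable days).
#' @param bouts_per_day,bout_rate_log_sd mean walking bouts per day and the
#'   between-participant SD of its log (defaults 35 and 0.40).
#' @param bout_duration_mean,bout_duration_log_sd mean bout duration in
#'   minutes and the between-participant SD of its log (defaults 4.75 and
#'   0.30).
#' @param cadence_mean,cadence_between_sd,cadence_within_sd mean bout cadence
#'   (steps/min), its between-participant SD, and the bout-to-bout SD within
#'   a participant (defaults 28, 5, 4).
#' @param brisk_share,brisk_boost_mean,brisk_boost_sd fraction of bouts walked
#'   briskly and the mean/SD of the per-participant brisk cadence bonus
#'   (defaults 0.1, 22, 16).
#' @param slow_share_mean,slow_share_sd mean/SD of the per-participant share
#'   of slow shuffling bouts (defaults 0.25, 0.15).
#' @param slow_cadence cadence of slow bouts in steps/min (default 10).
#' @param clusters_mean,clusters_sd mean and SD of the number of daily
#'   activity periods walking concentrates into (defaults 3.5, 1.8).
#' @param wake_sd between-participant SD of daily wear-window length in
#'   minutes (default 70, around a 960-min mean).
#' @param gap_prob_per_day probability a day contains an extra daytime
#'   non-wear gap of 240--420 min (default 0.08).
#' @param covariate_distributions list overriding any of `age_mean`, `age_sd`,
#'   `prop_female`, `race_probs` (named white/black/other),
#'   `mss_meanlog`, `mss_sdlog`, `sixmwt_mean`, `sixmwt_sd`,
#'   `sixmwt_mobility_cor`.
#' @param seed master seed for the cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 276L,
                          coef_map = c(avg_bout_cadence = -0.2,
                                       avg_long_sedentary_bouts_per_day = 0.2,
                                       age = 0.22, gender = -0.12,
                                       race_black = 0.165),
                          noise_sd = NULL,
                          sbp_mean = 128.13, sbp_sd = 16.26,
                          predictor_correlation = 0.4,
                          n_days = 9L,
                          bouts_per_day = 35, bout_rate_log_sd = 0.40,
                          bout_duration_mean = 4.75, bout_duration_log_sd = 0.30,
                          cadence_mean = 28, cadence_between_sd = 5,
                          cadence_within_sd = 4,
                          brisk_share = 0.1, brisk_boost_mean = 22,
                          brisk_boost_sd = 16,
                          slow_share_mean = 0.25, slow_share_sd = 0.15,
                          slow_cadence = 10,
                          clusters_mean = 3.5, clusters_sd = 1.8,
                          wake_sd = 70,
                          gap_prob_per_day = 0.08,
                          covariate_distributions = list(),
                          seed = NULL) {
  n_participants <- as.integer(n_participants)
  if (is.na(n_participants) || n_participants < 1L) {
    stop("n_participants must be a positive integer")
  }
  allowed <- c(measure_names(), "age", "gender", "race_black", "race_other",
               "months_since_stroke", "sixmwt_m")
  bad <- setdiff(names(coef_map), allowed)
  if (length(bad)) {
    stop("coef_map names must be activity measures or covariates; unknown: ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(noise_sd) && noise_sd <= 0) stop("noise_sd must be > 0")
  if (predictor_correlation < 0 || predictor_correlation >= 1) {
    stop("predictor_correlation must be in [0, 1)")
  }
  n_par <- length(coef_map) + 2L   # slopes + intercept + residual variance
  if (n_participants < n_par + 2L) {
    stop("n_participants must be at least the number of model parameters + 2 (",
         n_par + 2L, ")")
  }
  cov_dist <- utils::modifyList(
    list(age_mean = 65, age_sd = 12.6, prop_female = 0.482,
         race_probs = c(white = 0.612, black = 0.232, other = 0.156),
         mss_meanlog = log(23), mss_sdlog = 1.0,
         sixmwt_mean = 311.87, sixmwt_sd = 135,
         sixmwt_mobility_cor = 0.6),
    covariate_distributions
  )
  structure(
    list(n_participants = n_participants, coef_map = coef_map,
         noise_sd = noise_sd, sbp_mean = sbp_mean, sbp_sd = sbp_sd,
         predictor_correlation = predictor_correlation,
         n_days = as.integer(n_days),
         bouts_per_day = bouts_per_day, bout_rate_log_sd = bout_rate_log_sd,
         bout_duration_mean = bout_duration_mean,
         bout_duration_log_sd = bout_duration_log_sd,
         cadence_mean = cadence_mean,
         cadence_between_sd = cadence_between_sd,
         cadence_within_sd = cadence_within_sd,
         brisk_share = brisk_share, brisk_boost_mean = brisk_boost_mean,
         brisk_boost_sd = brisk_boost_sd,
         slow_share_mean = slow_share_mean, slow_share_sd = slow_share_sd,
         slow_cadence = slow_cadence,
         clusters_mean = clusters_mean, clusters_sd = clusters_sd,
         wake_sd = wake_sd,
         gap_prob_per_day = gap_prob_per_day,
         covariate_distributions = cov_dist,
         seed = seed),
    class = "cohort_config"
  )
}

# Random non-overlapping placement of items inside [start, start + width):
# items are ordered by the supplied location fractions q in [0, 1] and the
# free space is spread according to the sorted fractions. Returns start
# minutes in the items' original order.
place_segments <- function(lengths, q, start, width) {
  k <- length(lengths)
  if (k == 0L) return(integer(0))
  free <- width - sum(lengths)
  if (free < 0) stop("configured segments exceed the available window")
  ord <- order(q)
  starts <- integer(k)
  starts[ord] <- start + pmin(floor(sort(q) * (free + 1)), free) +
    c(0, cumsum(lengths[ord]))[seq_len(k)]
  starts
}

# Build one participant's series profile from latent channels.
participant_profile <- function(cfg, id, ch, seed) {
  wake_len <- as.integer(min(1110, max(840, round(960 + cfg$wake_sd * ch["wake"]))))
  wake_start <- as.integer(max(60L, min(round(480 - (wake_len - 960) / 2),
                                        1440L - wake_len)))
  rate <- cfg$bouts_per_day * exp(cfg$bout_rate_log_sd * ch["bout"])
  dur_mean <- max(1.2, cfg$bout_duration_mean *
                    exp(cfg$bout_duration_log_sd * ch["dur"]))
  cad_i <- max(5, cfg$cadence_mean + cfg$cadence_between_sd * ch["cad"])
  brisk_i <- max(0, cfg$brisk_boost_mean + cfg$brisk_boost_sd * ch["brisk"])
  slow_i <- min(0.6, max(0, cfg$slow_share_mean + cfg$slow_share_sd * ch["slow"]))
  n_clusters <- max(1L, round(cfg$clusters_mean + cfg$clusters_sd * ch["cluster"]))

  bouts <- list()
  gaps <- list()
  for (d in seq_len(cfg$n_days)) {
    gap_len <- if (runif(1) < cfg$gap_prob_per_day) {
      as.integer(round(runif(1, 240, 420)))
    } else 0L
    nb <- rpois(1, rate)
    durs <- 1L + rpois(nb, dur_mean - 1)
    # thin the day if the configured segments would overfill the wake window
    while (gap_len + sum(durs) > 0.9 * wake_len && length(durs) > 1L) {
      durs <- durs[-length(durs)]
    }
    nb <- length(durs)
    # bout locations concentrate into a few activity periods per day
    centers <- runif(n_clusters)
    qb <- pmin(1, pmax(0, centers[sample.int(n_clusters, nb, replace = TRUE)] +
                         rnorm(nb, 0, 0.04)))
    lens <- durs
    qs <- qb
    if (gap_len > 0L) {
      lens <- c(gap_len, durs)
      qs <- c(runif(1), qb)
    }
    starts <- place_segments(lens, qs, wake_start, wake_len)
    if (gap_len > 0L) {
      gaps[[length(gaps) + 1L]] <- c(d, starts[1L], gap_len)
      starts <- starts[-1L]
    }
    if (nb > 0L) {
      is_brisk <- runif(nb) < cfg$brisk_share
      is_slow <- !is_brisk & runif(nb) < slow_i
      cads <- pmax(2, rnorm(nb, cad_i, cfg$cadence_within_sd) + brisk_i * is_brisk)
      cads[is_slow] <- pmax(2, rnorm(sum(is_slow), cfg$slow_cadence, 2))
      for (i in seq_len(nb)) {
        bouts[[length(bouts) + 1L]] <- c(d, starts[i], durs[i], cads[i])
      }
    }
  }
  series_profile(n_days = cfg$n_days, wake_minutes_per_day = wake_len,
                 wake_start = wake_start, nonwear_gaps = gaps,
                 walking_bouts = bouts, participant_id = id, seed = seed)
}

#' Generate a synthetic cohort with planted outcome structure
#'
#' Draws covariates and latent activity channels per participant, realizes a
#' full minute-epoch step series for each, runs the actual processing pipeline
#' (non-wear detection, classification, valid days, activity measures), and
#' then generates SBP as a linear combination of the standardized realized
#' predictors named in `coef_map` plus Gaussian noise:
#' `SBP = sbp_mean + sbp_sd * sum(beta_j * z_j) + e`. The planted
#' coefficients are stored for parameter-recovery testing.
#'
#' @param cfg a [cohort_config()].
#' @param keep_series keep the per-participant step series in the result
#'   (default `TRUE`; set `FALSE` to save memory when only the measures are
#'   needed).
#' @param nonwear [nonwear_params()] used when processing the generated
#'   series.
#' @param min_wear_minutes,exclude_edge_days valid-day rule used in
#'   processing.
#' @return A list of class `walkbp_cohort` with elements `cohort` (covariate
#'   table with `sbp_mmhg`), `measures` (ten activity measures per
#'   participant), `series` (list of step-series data frames, or `NULL`),
#'   `profiles` (list of [series_profile()] objects), and `truth` (planted
#'   `coef_map`, realized `noise_sd`, `sbp_mean`, `sbp_sd`).
#' @export
generate_cohort <- function(cfg, keep_series = TRUE,
                            nonwear = nonwear_params(),
                            min_wear_minutes = 600L, exclude_edge_days = TRUE) {
  stopifnot(inherits(cfg, "cohort_config"))
  n <- cfg$n_participants
  cd <- cfg$covariate_distributions
  with_seed(cfg$seed, {
    mobility <- rnorm(n)
    rho <- cfg$predictor_correlation
    lat <- function(r) sqrt(r) * mobility + sqrt(1 - r) * rnorm(n)
    # core activity channels share the mobility factor at predictor_correlation;
    # shape channels (clustering, brisk reserve, wear duration) are independent
    channels <- cbind(bout = lat(rho), dur = lat(rho), cad = lat(rho),
                      cluster = rnorm(n), brisk = rnorm(n),
                      slow = rnorm(n), wake = rnorm(n))

    age <- pmin(85, pmax(21, round(rnorm(n, cd$age_mean, cd$age_sd))))
    gender <- ifelse(rbinom(n, 1, cd$prop_female) == 1L, "female", "male")
    race <- sample(names(cd$race_probs), n, replace = TRUE, prob = cd$race_probs)
    months_since_stroke <- pmax(6, round(rlnorm(n, cd$mss_meanlog, cd$mss_sdlog)))
    r6 <- cd$sixmwt_mobility_cor
    sixmwt_m <- pmax(20, round(cd$sixmwt_mean +
      cd$sixmwt_sd * (r6 * mobility + sqrt(1 - r6^2) * rnorm(n)), 1))
    ids <- sprintf("P%03d", seq_len(n))
    seeds <- sample.int(.Machine$integer.max - 64L, n)

    profiles <- vector("list", n)
    series <- if (keep_series) vector("list", n) else NULL
    meas <- vector("list", n)
    valid_ok <- logical(n)
    for (i in seq_len(n)) {
      # a draw can land below the valid-day minimum (heavy gaps, short wear
      # windows); such recordings would be excluded in a real study, so the
      # participant's recording is redrawn (bounded, seed-deterministic)
      for (attempt in 0:9) {
        profiles[[i]] <- participant_profile(cfg, ids[i], channels[i, ],
                                             seeds[i] + attempt)
        gen <- generate_step_series(profiles[[i]])
        labels <- classify_minutes(gen$series, nonwear)
        vd <- determine_valid_days(gen$series, labels, min_wear_minutes,
                                   exclude_edge_days)
        valid_ok[i] <- !vd$below_minimum
        if (valid_ok[i]) break
      }
      if (!valid_ok[i]) {
        stop("participant ", ids[i], " fell below the valid-day minimum in ",
             "10 consecutive draws (reduce gap_prob_per_day or increase n_days)")
      }
      meas[[i]] <- activity_measures(gen$series, labels, vd)
      if (keep_series) series[[i]] <- gen$series
    }
    measures <- do.call(rbind, meas)

    cohort <- data.frame(participant_id = ids, age = age, gender = gender,
                         race = race, months_since_stroke = months_since_stroke,
                         sixmwt_m = sixmwt_m, stringsAsFactors = FALSE)

    pred <- cbind(
      as.matrix(measures[measure_names()]),
      age = age,
      gender = as.numeric(gender == "female"),
      race_black = as.numeric(race == "black"),
      race_other = as.numeric(!race %in% c("white", "black")),
      months_since_stroke = months_since_stroke,
      sixmwt_m = sixmwt_m
    )
    if (anyNA(pred[, names(cfg$coef_map), drop = FALSE])) {
      stop("undefined activity measures in generated cohort; ",
           "cannot apply the planted coefficient map")
    }
    f <- if (length(cfg$coef_map)) {
      z <- standardize_predictors(pred[, names(cfg$coef_map), drop = FALSE])
      as.vector(z %*% cfg$coef_map)
    } else rep(0, n)
    noise_sd <- cfg$noise_sd
    if (is.null(noise_sd)) {
      noise_sd <- cfg$sbp_sd * sqrt(max(0.1, 1 - stats::var(f)))
    }
    cohort$sbp_mmhg <- cfg$sbp_mean + cfg$sbp_sd * f + rnorm(n, 0, noise_sd)

    structure(
      list(cohort = cohort, measures = measures, series = series,
           profiles = profiles,
           truth = list(coef_map = cfg$coef_map, noise_sd = noise_sd,
                        sbp_mean = cfg$sbp_mean, sbp_sd = cfg$sbp_sd)),
      class = "walkbp_cohort"
    )
  })
}

#' @export
print.walkbp_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$cohort), "participants\n")
  if (length(x$truth$coef_map)) {
    cat("  planted standardized effects:\n")
    for (nm in names(x$truth$coef_map)) {
      cat(sprintf("    %-34s %+0.3f\n", nm, x$truth$coef_map[[nm]]))
    }
  } else cat("  no planted effects (null cohort)\n")
  cat(sprintf("  SBP %.1f mmHg (scale %.2f), residual SD %.2f mmHg\n",
              x$truth$sbp_mean, x$truth$sbp_sd, x$truth$noise_sd))
  invisible(x)
}
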