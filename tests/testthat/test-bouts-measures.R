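test_that("bouts are maximal same-label runs with correct step totals", {
  s <- step_series(1, 0:5, c(10, 20, 30, 0, 0, 5))
  lab <- c("active", "active", "active", "sedentary", "sedentary", "active")
  b <- extract_bouts(s, lab)
  expect_equal(nrow(b), 3)
  walking <- b[b$kind == "walking", ]
  expect_equal(walking$total_steps, c(60, 5))
  expect_equal(walking$duration_minutes, c(3, 1))
  expect_equal(walking$cadence, c(20, 5))
  expect_equal(b$duration_minutes[b$kind == "sedentary"], 2)
  expect_equal(b$total_steps[b$kind == "sedentary"], 0)
})

test_that("bout extraction handles degenerate and boundary cases", {
  # an all-sedentary stretch is one bout
  s <- step_series(1, 0:599, rep(0, 600))
  b <- extract_bouts(s, rep("sedentary", 600))
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_minutes, 600)
  # no wear time -> empty bout list
  b0 <- extract_bouts(s, rep("nonwear", 600))
  expect_equal(nrow(b0), 0)
  # non-wear and recording breaks terminate bouts
  s2 <- step_series(1, c(0:2, 10:12), rep(5, 6))
  b2 <- extract_bouts(s2, rep("active", 6))
  expect_equal(nrow(b2), 2)
  s3 <- step_series(1, 0:4, c(5, 5, 0, 5, 5))
  b3 <- extract_bouts(s3, c("active", "active", "nonwear", "active", "active"))
  expect_equal(nrow(b3), 2)
})

test_that("step and minute totals are conserved between minutes and bouts", {
  set.seed(11)
  for (i in 1:15) {
    s <- random_series(sample(600:2500, 1))
    lab <- classify_minutes(s)
    b <- extract_bouts(s, lab)
    expect_equal(sum(b$total_steps[b$kind == "walking"]),
                 sum(s$steps[lab == "active"]))
    expect_equal(sum(b$duration_minutes), sum(lab != "nonwear"))
    ref <- naive_bouts(s$steps, lab)
    expect_equal(nrow(b), nrow(ref))
    expect_equal(b$duration_minutes, ref$duration_minutes)
    expect_equal(b$total_steps, ref$total_steps)
    if (any(b$kind == "walking")) {
      expect_true(all(b$cadence[b$kind == "walking"] >= 1))
    }
  }
})

# A compact two-day fixture with hand-computable measures, built from labels.
fixture_two_days <- function() {
  # day 1: bout of 39 steps (3 min), bout of 300 steps (10 min), rest sedentary
  # day 2: bout of 1000 steps in 20 min, bout of 961 in 10, rest sedentary
  steps1 <- c(rep(13, 3), 0, rep(30, 10), rep(0, 586))
  steps2 <- c(rep(50, 20), 0, rep(96, 9), 97, rep(0, 569))
  step_series(day = rep(1:2, each = 600), minute = rep(300:899, 2),
              steps = c(steps1, steps2))
}

test_that("volume and frequency measures follow the per-day ratios", {
  s <- fixture_two_days()
  lab <- ifelse(s$steps > 0, "active", "sedentary")
  vf <- compute_volume_frequency(s, lab, valid_days = 1:2)
  expect_equal(vf$avg_steps_per_day, (339 + 1961) / 2)  # 1150
  expect_equal(vf$avg_time_walking_per_day, (13 + 30) / 2)
  expect_equal(vf$avg_short_bouts_per_day, 0.5)   # the 39-step bout
  expect_equal(vf$avg_long_bouts_per_day, 1.5)    # 300, 1000 and 961 steps
  expect_equal(vf$avg_bouts_per_day, 2)
  # restricted to day 1 only
  vf1 <- compute_volume_frequency(s, lab, valid_days = 1)
  expect_equal(vf1$avg_steps_per_day, 339)
  expect_equal(vf1$avg_short_bouts_per_day, 1)
  expect_equal(vf1$avg_long_bouts_per_day, 1)
  expect_error(compute_volume_frequency(s, lab, integer(0)), "no valid")
})

test_that("intensity measures implement peak30 padding and pooled cadence", {
  # 30 active minutes of 10 steps, rest zeros -> peak30 = 10
  s <- step_series(1, 0:599, c(rep(10, 30), rep(0, 570)))
  lab <- ifelse(s$steps > 0, "active", "sedentary")
  it <- compute_intensity(s, lab, valid_days = 1)
  expect_equal(it$peak30, 10)
  # 20 wear minutes of 60 steps -> zero-padded: (20*60)/30 = 40
  s2 <- step_series(1, 0:19, rep(60, 20))
  it2 <- compute_intensity(s2, rep("active", 20), valid_days = 1)
  expect_equal(it2$peak30, 40)
  # bout cadences pooled over bouts, not days: (100/4 + 30/2)/2 = 20
  s3 <- step_series(1, 0:6, c(25, 25, 25, 25, 0, 15, 15))
  lab3 <- c(rep("active", 4), "sedentary", "active", "active")
  expect_equal(compute_intensity(s3, lab3, valid_days = 1)$avg_bout_cadence, 20)
  # peak30 pools wear minutes only: non-wear zeros are excluded
  s4 <- step_series(1, 0:299, c(rep(30, 30), rep(0, 270)))
  lab4 <- c(rep("active", 30), rep("nonwear", 270))
  expect_equal(compute_intensity(s4, lab4, valid_days = 1)$peak30, 30)
  # no walking bouts -> flagged missing cadence
  s5 <- step_series(1, 0:99, rep(0, 100))
  expect_true(is.na(compute_intensity(s5, rep("sedentary", 100), 1)$avg_bout_cadence))
})

test_that("sedentary measures implement the ratios and thresholds", {
  # 480 sedentary of 600 wear minutes -> 80%
  s <- step_series(1, 0:599, c(rep(5, 120), rep(0, 480)))
  lab <- ifelse(s$steps > 0, "active", "sedentary")
  sb <- compute_sedentary(s, lab, valid_days = 1)
  expect_equal(sb$percent_sedentary_time, 80)
  # sedentary bouts of 35, 10 and 4 min: one long bout, fragmentation 2/49
  steps <- c(5, rep(0, 35), 5, rep(0, 10), 5, rep(0, 4), 5)
  s2 <- step_series(1, seq_along(steps) - 1, steps)
  lab2 <- ifelse(steps > 0, "active", "sedentary")
  sb2 <- compute_sedentary(s2, lab2, valid_days = 1)
  expect_equal(sb2$avg_long_sedentary_bouts_per_day, 1)
  expect_equal(sb2$fragmentation_index, 2 / 49)
  # one unbroken 100-min sedentary bout -> 1/100
  s3 <- step_series(1, 0:100, c(5, rep(0, 100)))
  lab3 <- c("active", rep("sedentary", 100))
  expect_equal(compute_sedentary(s3, lab3, 1)$fragmentation_index, 0.01)
  # zero sedentary minutes -> flagged missing fragmentation
  s4 <- step_series(1, 0:9, rep(10, 10))
  sb4 <- compute_sedentary(s4, rep("active", 10), 1)
  expect_true(is.na(sb4$fragmentation_index))
  expect_equal(sb4$percent_sedentary_time, 0)
})

test_that("duplicating a day leaves all per-day averages unchanged", {
  set.seed(21)
  one <- random_series(1440)
  lab1 <- classify_minutes(one)
  two <- step_series(day = rep(1:2, each = 1440), minute = rep(0:1439, 2),
                     steps = rep(one$steps, 2))
  lab2 <- classify_minutes(two)
  # guard: duplication must not have created new cross-midnight structure
  skip_if_not(identical(lab2, rep(lab1, 2)))
  m1 <- activity_measures(one, lab1, valid_days = 1)
  m2 <- activity_measures(two, lab2, valid_days = 1:2)
  for (nm in measure_names()) expect_equal(m2[[nm]], m1[[nm]], info = nm)
})

test_that("the ten measures assemble with invariants satisfied", {
  p <- unambiguous_profile(n_days = 4, seed = 5)
  g <- generate_step_series(p)
  lab <- classify_minutes(g$series)
  vd <- determine_valid_days(g$series, lab, 600, exclude_edge_days = FALSE)
  m <- activity_measures(g$series, lab, vd)
  expect_true(all(m[measure_names()] >= 0, na.rm = TRUE))
  expect_true(m$percent_sedentary_time >= 0 && m$percent_sedentary_time <= 100)
  expect_lte(m$avg_short_bouts_per_day + m$avg_long_bouts_per_day,
             m$avg_bouts_per_day)
  expect_gte(m$avg_bout_cadence, 1)
  expect_equal(m$n_valid_days, 4)
})
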