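test_that("step-series validation rejects malformed input", {
  expect_error(validate_step_series(data.frame()), "non-empty")
  expect_error(step_series(1, c(0, 0), c(1, 2)), "strictly increasing")
  expect_error(step_series(1, 0:1, c(-1, 2)), "non-negative")
  expect_error(step_series(1, 0:1, c(0.5, 2)), "non-negative integers")
  expect_error(step_series(1, c(1, 0), c(0, 0)), "strictly increasing")
  expect_error(detect_nonwear(step_series(1, 0, 0), nonwear_params()),
               NA) # single minute is valid input
})

test_that("printed worked examples classify exactly as stated", {
  s1 <- step_series(1, 0:2, c(0, 1, 0))
  expect_equal(classify_active_sedentary(s1, rep("wear", 3)),
               c("sedentary", "sedentary", "sedentary"))
  s2 <- step_series(1, 0:3, c(10, 12, 0, 20))
  expect_equal(classify_active_sedentary(s2, rep("wear", 4)),
               c("active", "active", "sedentary", "active"))
  s3 <- step_series(1, 0:2, c(0, 2, 0))
  expect_equal(classify_active_sedentary(s3, rep("wear", 3)),
               c("sedentary", "active", "sedentary"))
})

test_that("the single-step exception respects boundaries and non-wear neighbors", {
  # isolated 1 at the start/end of recording counts as flanked by zeros
  s <- step_series(1, 0:2, c(1, 0, 5))
  expect_equal(classify_active_sedentary(s, rep("wear", 3))[1], "sedentary")
  s <- step_series(1, 0:2, c(5, 0, 1))
  expect_equal(classify_active_sedentary(s, rep("wear", 3))[3], "sedentary")
  # a non-wear neighbor counts as a zero-step neighbor
  s <- step_series(1, 0:2, c(0, 1, 3))
  lab <- classify_active_sedentary(s, c("nonwear", "wear", "wear"))
  expect_equal(lab, c("nonwear", "active", "active"))  # right neighbor has 3 steps
  s <- step_series(1, 0:2, c(0, 1, 0))
  lab <- classify_active_sedentary(s, c("nonwear", "wear", "wear"))
  expect_equal(lab[2], "sedentary")
  # classification is idempotent on its own output
  s <- random_series(1500)
  lab1 <- classify_minutes(s, nonwear_params())
  expect_identical(classify_active_sedentary(s, lab1), lab1)
})

test_that("non-wear detection follows the windowed rule with spurious allowance", {
  p <- nonwear_params()
  # 240 zeros flanked by activity
  s <- step_series(1, 0:241, c(10, rep(0, 240), 10))
  lab <- detect_nonwear(s, p)
  expect_equal(lab, c("wear", rep("nonwear", 240), "wear"))
  # 239 zeros: below threshold
  s <- step_series(1, 0:240, c(10, rep(0, 239), 10))
  expect_true(all(detect_nonwear(s, p) == "wear"))
  # 300 zeros containing two isolated 2-step minutes -> all non-wear
  z <- rep(0L, 300); z[c(100, 200)] <- 2L
  s <- step_series(1, 0:301, c(10, z, 10))
  expect_equal(sum(detect_nonwear(s, p) == "nonwear"), 300)
  # three spurious minutes placed so no 240-min sub-window holds <= 2 -> wear
  z <- rep(0L, 300); z[c(75, 150, 225)] <- 2L
  s <- step_series(1, 0:301, c(10, z, 10))
  expect_true(all(detect_nonwear(s, p) == "wear"))
  # interval endpoints must be zero-step: a leading spurious minute is not absorbed
  z <- c(2L, rep(0L, 240))
  s <- step_series(1, 0:242, c(10, z, 10))
  lab <- detect_nonwear(s, p)
  expect_equal(lab[2], "wear")          # the 2-step minute itself
  expect_true(all(lab[3:242] == "nonwear"))
  # a 3-step minute can never sit inside a non-wear interval
  z <- rep(0L, 300); z[150] <- 3L
  s <- step_series(1, 0:299, z)
  lab <- detect_nonwear(s, p)
  expect_equal(lab[150], "wear")
  expect_true(all(lab[-150] == "wear"))  # neither side reaches 240 minutes
})

test_that("non-wear intervals span midnight but not recording breaks", {
  # 318 zeros spanning the day-1/day-2 boundary
  s <- step_series(day = rep(1:2, each = 160),
                   minute = c(1280:1439, 0:159),
                   steps = c(5, rep(0, 318), 5))
  expect_equal(sum(detect_nonwear(s) == "nonwear"), 318)
  # same minutes with day 2 recording starting at minute 100: a gap in
  # recording breaks the interval
  s2 <- step_series(day = rep(1:2, each = 160),
                    minute = c(1280:1439, 100:259),
                    steps = c(5, rep(0, 318), 5))
  expect_true(all(detect_nonwear(s2) == "wear"))
})

test_that("detect_nonwear matches the brute-force sub-interval checker", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(300:2000, 1)
    s <- random_series(n)
    mine <- detect_nonwear(s) == "nonwear"
    ref <- brute_force_nonwear(s$steps)
    expect_identical(mine, ref)
  }
  # also at non-default parameters
  set.seed(43)
  p <- nonwear_params(window_minutes = 90, spurious_allowance = 1,
                      spurious_max_steps = 1)
  for (i in 1:10) {
    s <- random_series(800)
    expect_identical(detect_nonwear(s, p) == "nonwear",
                     brute_force_nonwear(s$steps, p))
  }
})

test_that("labels always partition the series", {
  set.seed(7)
  for (i in 1:10) {
    s <- random_series(sample(500:2500, 1))
    lab <- classify_minutes(s)
    expect_equal(sum(lab == "nonwear") + sum(lab == "active") +
                   sum(lab == "sedentary"), nrow(s))
    expect_true(all(s$steps[lab == "active"] >= 1))
  }
})

test_that("valid days are counted by wear minutes with edge-day exclusion", {
  # 7 days, each with 900 wear minutes (wear encoded through steps > 0 labels)
  s <- step_series(day = rep(1:7, each = 1440), minute = rep(0:1439, 7),
                   steps = 0)
  lab <- rep(rep(c("sedentary", "nonwear"), c(900, 540)), 7)
  vd <- determine_valid_days(s, lab, 600, exclude_edge_days = TRUE)
  expect_equal(vd$n_valid, 5)
  expect_equal(vd$valid_days, 2:6)
  expect_false(vd$below_minimum)
  vd2 <- determine_valid_days(s, lab, 600, exclude_edge_days = FALSE)
  expect_equal(vd2$n_valid, 7)
  # a day with zero wear minutes is invalid even at threshold 1
  lab3 <- lab; lab3[s$day == 4] <- "nonwear"
  vd3 <- determine_valid_days(s, lab3, 600, exclude_edge_days = TRUE)
  expect_equal(vd3$valid_days, c(2, 3, 5, 6))
  # fewer than 3 valid days flags the participant
  vd4 <- determine_valid_days(s, lab, 1000)
  expect_true(vd4$below_minimum)
  expect_error(determine_valid_days(s, lab, 2000), "1440")
})

test_that("window sweep behaves per the rule and is monotone", {
  # single 250-min zero gap: non-wear at window 240, none at 300
  s <- step_series(1, 0:299, c(rep(5, 25), rep(0, 250), rep(5, 25)))
  sw <- sweep_nonwear_windows(s, c(180, 240, 300, 360))
  expect_equal(sw$nonwear_minutes, c(250, 250, 0, 0))
  expect_true(all(diff(sw$nonwear_minutes) <= 0))
  # all-zero day: everything is non-wear at any window <= 1440
  s0 <- step_series(1, 0:1439, rep(0, 1440))
  sw0 <- sweep_nonwear_windows(s0, c(180, 240, 300, 360, 1440))
  expect_true(all(sw0$nonwear_minutes == 1440))
  expect_error(sweep_nonwear_windows(s, integer(0)), "non-empty")
})

test_that("percent agreement is an exact three-way match rate", {
  a <- rep(c("active", "sedentary", "nonwear"), length.out = 100)
  expect_equal(percent_agreement(a, a), 100)
  b <- a
  b[1:6] <- ifelse(a[1:6] == "active", "sedentary", "active")
  expect_equal(percent_agreement(b, a), 94)
  expect_equal(percent_agreement(rep("active", 10), rep("nonwear", 10)), 0)
  expect_error(percent_agreement(a, a[-1]), "length")
})
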