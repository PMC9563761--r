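#' Aggregate resting blood-pressure readings
#'
#' Resting blood pressure is the mean of the first two readings; when they
#' differ by more than 5 mmHg a third reading is required and the mean of all
#' provided readings is used instead.
#'
#' @param readings ordered numeric vector of systolic readings (mmHg), at
#'   least two.
#' @param max_diff difference (mmHg) above which an additional reading is
#'   required (default 5).
#' @return The aggregated resting value in mmHg.
#' @examples
#' aggregate_resting_bp(c(120, 122))       # 121
#' aggregate_resting_bp(c(120, 128, 124))  # 124
#' @export
aggregate_resting_bp <- function(readings, max_diff = 5) {
  if (!is.numeric(readings) || length(readings) < 2L || anyNA(readings)) {
    stop("at least two non-missing readings are required")
  }
  if (abs(readings[1L] - readings[2L]) <= max_diff) {
    mean(readings[1:2])
  } else {
    if (length(readings) < 3L) {
      stop("first two readings differ by more than ", max_diff,
           " mmHg; an additional reading is required")
    }
    mean(readings)
  }
}

#' Filter a cohort on systolic blood-pressure eligibility
#'
#' Retains participants whose SBP lies within the eligibility bounds
#' (defaults 90--170 mmHg) and logs each exclusion with its reason.
#'
#' @param cohort data frame with an SBP column.
#' @param sbp_min,sbp_max inclusive bounds in mmHg (defaults 90 and 170).
#' @param sbp_col name of the SBP column (default `"sbp_mmhg"`).
#' @return A list with `cohort` (retained rows) and `exclusions` (data frame
#'   of excluded rows with a `reason` column; zero rows when none).
#' @export
filter_eligibility <- function(cohort, sbp_min = 90, sbp_max = 170,
                               sbp_col = "sbp_mmhg") {
  if (!sbp_col %in% names(cohort)) stop("cohort has no column ", sbp_col)
  sbp <- cohort[[sbp_col]]
  low <- !is.na(sbp) & sbp < sbp_min
  high <- !is.na(sbp) & sbp > sbp_max
  keep <- !is.na(sbp) & !low & !high
  reason <- rep(NA_character_, nrow(cohort))
  reason[low] <- sprintf("SBP %.1f below eligibility minimum %g", sbp[low], sbp_min)
  reason[high] <- sprintf("SBP %.1f above eligibility maximum %g", sbp[high], sbp_max)
  reason[is.na(sbp)] <- "SBP missing"
  excl <- cohort[!keep, , drop = FALSE]
  excl$reason <- reason[!keep]
  list(cohort = cohort[keep, , drop = FALSE], exclusions = excl)
}

#' Prepare a cohort table for regression
#'
#' Joins the covariate table with the activity measures (on
#' `participant_id`), codes gender as 0 = male / 1 = female, and dummy-codes
#' race against a white reference (`race_black`, `race_other`); any race
#' level other than white or black -- including declined responses -- is
#' merged into other.
#'
#' @param cohort covariate data frame (`age`, `gender`, `race`,
#'   `months_since_stroke`, `sixmwt_m`, `sbp_mmhg`).
#' @param measures optional activity-measures data frame with
#'   `participant_id`.
#' @return A data frame with numeric `gender`, `race_black`, `race_other`
#'   columns added (original `race` retained).
#' @export
prepare_regression_data <- function(cohort, measures = NULL) {
  df <- cohort
  if (!is.null(measures)) {
    df <- merge(df, measures, by = "participant_id", sort = FALSE)
  }
  g <- df$gender
  if (!is.numeric(g)) {
    g <- match(tolower(as.character(g)), c("male", "female")) - 1
    if (anyNA(g)) stop("gender must be male/female or 0/1")
  }
  df$gender <- g
  race <- tolower(as.character(df$race))
  df$race_black <- as.numeric(race == "black")
  df$race_other <- as.numeric(!race %in% c("white", "black"))
  df
}

#' Sequential (hierarchical) blockwise linear regression
#'
#' Enters predictors in ordered blocks and evaluates each block's
#' contribution by the change in R-squared:
#' `F = (dR2 / q) / ((1 - R2_cum) / (n - k - 1))` with `q` the block size and
#' `k` the cumulative number of predictors, referred to `F(q, n - k - 1)`.
#' The default block structure is covariates (age, gender, race dummies, time
#' since stroke), then walking capacity (6-Minute Walk Test), then the
#' selected activity measures. Standardized coefficients of the full model
#' are `b * sd(x) / sd(y)` using sample SDs of the analysis sample.
#'
#' Complete cases only: rows with missing values in any used column are
#' dropped (their count is reported in the result).
#'
#' @param data regression-ready data frame (see [prepare_regression_data()]).
#' @param blocks named list of character vectors of column names, in entry
#'   order.
#' @param response response column name (default `"sbp_mmhg"`).
#' @return A list of class `walkbp_seqreg`: `blocks` (per block: `r2`,
#'   `delta_r2`, `f`, `df1`, `df2`, `p`, and the cumulative-model `model_p`),
#'   `coefficients` (full model: raw `estimate`, `std_beta`, `p` per
#'   predictor), `r2` (full model), `n`, `n_dropped`.
#' @export
fit_sequential <- function(data,
                           blocks = list(
                             covariates = c("age", "gender", "race_black",
                                            "race_other", "months_since_stroke"),
                             walking_capacity = "sixmwt_m",
                             activity_measures = c("avg_bout_cadence",
                                                   "avg_long_sedentary_bouts_per_day")),
                           response = "sbp_mmhg") {
  vars <- unique(unlist(blocks))
  miss <- setdiff(c(vars, response), names(data))
  if (length(miss)) stop("data is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(unlist(blocks))) stop("blocks must not share predictors")
  df <- data[c(response, vars)]
  cc <- stats::complete.cases(df)
  n_dropped <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  n <- nrow(df)
  k_total <- length(vars)
  if (n <= k_total + 1L) stop("too few complete cases for the full model")

  X <- as.matrix(df[vars])
  y <- df[[response]]
  qrX <- qr(cbind(1, X))
  if (qrX$rank < k_total + 1L) {
    aliased <- vars[qrX$pivot[seq.int(qrX$rank + 1L, k_total + 1L)] - 1L]
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "))
  }

  tss <- sum((y - mean(y))^2)
  cum_vars <- character(0)
  prev_r2 <- 0
  rows <- list()
  for (b in seq_along(blocks)) {
    cum_vars <- c(cum_vars, blocks[[b]])
    q <- length(blocks[[b]])
    k <- length(cum_vars)
    fit <- stats::lm.fit(cbind(1, X[, cum_vars, drop = FALSE]), y)
    r2 <- 1 - sum(fit$residuals^2) / tss
    d_r2 <- r2 - prev_r2
    df2 <- n - k - 1L
    fstat <- (d_r2 / q) / ((1 - r2) / df2)
    model_f <- (r2 / k) / ((1 - r2) / df2)
    rows[[b]] <- data.frame(
      block = names(blocks)[b],
      predictors = paste(blocks[[b]], collapse = ", "),
      r2 = r2, delta_r2 = d_r2, f = fstat, df1 = q, df2 = df2,
      p = stats::pf(fstat, q, df2, lower.tail = FALSE),
      model_p = stats::pf(model_f, k, df2, lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
    prev_r2 <- r2
  }
  block_tab <- do.call(rbind, rows)

  full <- stats::lm(stats::reformulate(sprintf("`%s`", vars),
                                       response = sprintf("`%s`", response)),
                    data = df)
  sm <- summary(full)$coefficients
  est <- coef(full)[-1L]
  coef_tab <- data.frame(
    term = vars,
    estimate = as.vector(est),
    std_beta = as.vector(est) * apply(X, 2, stats::sd) / stats::sd(y),
    p = sm[-1L, "Pr(>|t|)"],
    stringsAsFactors = FALSE
  )
  rownames(coef_tab) <- NULL

  structure(
    list(blocks = block_tab, coefficients = coef_tab,
         r2 = prev_r2, n = n, n_dropped = n_dropped, response = response),
    class = "walkbp_seqreg"
  )
}

#' @export
print.walkbp_seqreg <- function(x, digits = 3, ...) {
  cat(sprintf("Sequential regression of %s (n = %d%s)\n", x$response, x$n,
              if (x$n_dropped) sprintf(", %d incomplete rows dropped", x$n_dropped) else ""))
  b <- x$blocks
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  block %d [%s]: R2 = %.3f, dR2 = %.3f, F(%d, %d) = %.2f, p = %.4g\n",
                i, b$block[i], b$r2[i], b$delta_r2[i], b$df1[i], b$df2[i],
                b$f[i], b$p[i]))
  }
  cat(sprintf("  full model R2 = %.3f\n", x$r2))
  cat("  standardized coefficients (full model):\n")
  co <- x$coefficients
  for (i in seq_len(nrow(co))) {
    cat(sprintf("    %-34s beta = %+0.3f  p = %.4g\n",
                co$term[i], co$std_beta[i], co$p[i]))
  }
  invisible(x)
}
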