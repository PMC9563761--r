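#' Exhaustive best-subset regression
#'
#' Fits ordinary least squares for every subset of the predictor columns
#' (all `2^p` subsets, including the intercept-only model) and records the
#' residual sum of squares, AIC and adjusted R-squared of each. Three winners
#' are reported: the subset with the lowest AIC, the subset with the highest
#' adjusted R-squared, and -- because RSS always favors the full model -- the
#' lowest-RSS subset restricted to a given size (`rss_size`, typically the
#' number of predictors the lasso retained).
#'
#' AIC uses the Gaussian log-likelihood convention of `stats::AIC()`:
#' `n*(log(2*pi) + 1) + n*log(RSS/n) + 2*(m + 2)` for a subset of `m`
#' predictors (intercept and error variance count as parameters); only
#' differences between subsets matter for ranking. Numerically-zero residual
#' sums of squares are floored at `TSS * 1e-12` so that exact fits rank by
#' parsimony rather than by rounding noise. Subsets with singular normal
#' equations are flagged, excluded from the ranking and counted.
#'
#' @param x predictor matrix or data frame (at most 20 columns).
#' @param y response vector.
#' @param rss_size subset size for the restricted lowest-RSS winner; `NULL`
#'   omits that winner, `0` makes it the intercept-only (empty) model.
#' @return A list of class `subset_enumeration`: `table` (one row per
#'   subset: `members`, `size`, `rss`, `aic`, `adj_r2`), `winners` (list of
#'   character vectors `aic`, `adj_r2`, `rss`), `rss_size`, `n_singular`,
#'   `n`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- x[, "b"] + rnorm(100)
#' enumerate_best_subsets(x, y, rss_size = 1)$winners
#' @export
enumerate_best_subsets <- function(x, y, rss_size = NULL) {
  x <- as.matrix(x)
  p <- ncol(x)
  n <- nrow(x)
  if (p > 20L) stop("exhaustive enumeration supports at most 20 predictors")
  if (n <= p + 2L) stop("need n > p + 2 observations for the full model")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(p))
  nms <- colnames(x)

  X1 <- cbind(1, x)
  G <- crossprod(X1)
  g <- as.vector(crossprod(X1, y))
  yty <- sum(y^2)
  tss <- yty - n * mean(y)^2
  rss_floor <- tss * 1e-12

  nsub <- 2L^p
  masks <- 0:(nsub - 1L)
  bits <- 2L^(0:(p - 1L))
  size <- integer(nsub)
  rss <- aic <- adj <- rep(NA_real_, nsub)
  members <- character(nsub)
  singular <- logical(nsub)
  const <- n * (log(2 * pi) + 1)

  for (i in seq_len(nsub)) {
    cols <- which(bitwAnd(masks[i], bits) > 0L)
    m <- length(cols)
    size[i] <- m
    members[i] <- paste(nms[cols], collapse = ",")
    idx <- c(1L, cols + 1L)
    sol <- tryCatch(solve(G[idx, idx, drop = FALSE], g[idx]),
                    error = function(e) NULL)
    if (is.null(sol)) {
      singular[i] <- TRUE
      next
    }
    r <- max(yty - sum(sol * g[idx]), rss_floor)
    rss[i] <- r
    aic[i] <- const + n * log(r / n) + 2 * (m + 2)
    adj[i] <- 1 - (r / (n - m - 1)) * ((n - 1) / tss)
  }

  tab <- data.frame(members = members, size = size, rss = rss, aic = aic,
                    adj_r2 = adj, stringsAsFactors = FALSE)
  split_members <- function(i) {
    if (is.na(i) || members[i] == "") character(0) else strsplit(members[i], ",")[[1]]
  }
  ok <- !singular
  win_aic <- split_members(which(ok)[which.min(aic[ok])])
  win_adj <- split_members(which(ok)[which.max(adj[ok])])
  win_rss <- NULL
  if (!is.null(rss_size)) {
    cand <- which(ok & size == rss_size)
    win_rss <- if (length(cand)) split_members(cand[which.min(rss[cand])]) else character(0)
  }
  structure(
    list(table = tab,
         winners = list(aic = win_aic, adj_r2 = win_adj, rss = win_rss),
         rss_size = rss_size, n_singular = sum(singular), n = n),
    class = "subset_enumeration"
  )
}

#' @export
print.subset_enumeration <- function(x, ...) {
  cat(sprintf("Best-subset enumeration: %d models over %d predictors (n = %d)\n",
              nrow(x$table), max(x$table$size), x$n))
  fmt <- function(s) if (length(s)) paste(s, collapse = ", ") else "(intercept only)"
  cat("  lowest AIC:          ", fmt(x$winners$aic), "\n")
  cat("  highest adjusted R2: ", fmt(x$winners$adj_r2), "\n")
  if (!is.null(x$winners$rss)) {
    cat(sprintf("  lowest RSS (size %d): %s\n", x$rss_size, fmt(x$winners$rss)))
  }
  if (x$n_singular > 0) cat("  singular subsets excluded:", x$n_singular, "\n")
  invisible(x)
}

#' Intersect the selected sets of all approaches
#'
#' Measures common to the lasso selection and the three best-subset winners.
#' An empty intersection is a valid, reported outcome.
#'
#' @param lasso_set,aic_set,adjr2_set,rss_set character vectors of selected
#'   predictor names.
#' @return A list of class `selection_result` with the per-method sets and
#'   their `intersection` (sorted).
#' @export
intersect_selections <- function(lasso_set, aic_set, adjr2_set, rss_set) {
  sets <- list(lasso = lasso_set, aic = aic_set, adj_r2 = adjr2_set,
               rss = rss_set)
  structure(
    c(sets, list(intersection = sort(Reduce(intersect, sets)))),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  fmt <- function(s) if (length(s)) paste(s, collapse = ", ") else "(none)"
  cat("Selected activity measures by method:\n")
  cat("  lasso (CV-optimal):  ", fmt(x$lasso), "\n")
  cat("  lowest AIC:          ", fmt(x$aic), "\n")
  cat("  highest adjusted R2: ", fmt(x$adj_r2), "\n")
  cat("  lowest RSS:          ", fmt(x$rss), "\n")
  cat("  common to all:       ", fmt(x$intersection), "\n")
  invisible(x)
}

#' Two-stage variable selection over the ten activity measures
#'
#' Standardizes the measures and the response (population-SD convention),
#' chooses the lasso penalty by replicated cross-validation and refits on all
#' data ([cross_validate_lambda()]), enumerates all best subsets
#' ([enumerate_best_subsets()]) with the RSS winner restricted to the lasso
#' subset size, and intersects the four selected sets.
#'
#' @param measures data frame or matrix of the ten activity measures (rows =
#'   participants); extra columns such as `participant_id` or `n_valid_days`
#'   are dropped automatically when the ten measure columns are present.
#' @param sbp systolic blood pressure vector aligned to the rows.
#' @param folds,replicates,grid_size,grid_min_ratio CV settings (defaults 10,
#'   100, 100, 1e-4).
#' @param seed seed for the CV fold partitions.
#' @return A list of class `walkbp_selection`: `cv` ([cross_validate_lambda()]
#'   result), `enumeration`, `selection` ([intersect_selections()] result),
#'   and `selected` (the intersection, for convenience).
#' @export
select_activity_measures <- function(measures, sbp, folds = 10L,
                                     replicates = 100L, grid_size = 100L,
                                     grid_min_ratio = 1e-4, seed = NULL) {
  m <- as.data.frame(measures)
  if (all(measure_names() %in% names(m))) m <- m[measure_names()]
  x <- standardize_predictors(as.matrix(m))
  if (anyNA(x)) stop("missing values in the activity measures; exclude incomplete participants first")
  y <- standardize_response(sbp)
  cv <- cross_validate_lambda(x, as.vector(y), folds = folds,
                              replicates = replicates, seed = seed,
                              grid_size = grid_size,
                              grid_min_ratio = grid_min_ratio)
  enum <- enumerate_best_subsets(x, as.vector(y),
                                 rss_size = length(cv$nonzero_set))
  sel <- intersect_selections(cv$nonzero_set, enum$winners$aic,
                              enum$winners$adj_r2, enum$winners$rss)
  structure(
    list(cv = cv, enumeration = enum, selection = sel,
         selected = sel$intersection),
    class = "walkbp_selection"
  )
}

#' @export
print.walkbp_selection <- function(x, ...) {
  print(x$cv)
  print(x$selection)
  invisible(x)
}
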