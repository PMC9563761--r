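test_that("standardization uses the population-SD convention", {
  x <- matrix(c(1, 2, 3), dimnames = list(NULL, "a"))
  z <- standardize_predictors(x)
  expect_equal(as.vector(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  # idempotent on already-standardized columns
  expect_equal(as.vector(standardize_predictors(z)), as.vector(z),
               tolerance = 1e-12)
  expect_error(standardize_predictors(cbind(a = rep(2, 5), b = 1:5)), "a")
})

test_that("lasso limits: OLS at zero penalty, exact zeros at lambda_max", {
  set.seed(101)
  x <- matrix(rnorm(1200), 200, 6)
  x <- x %*% chol(0.5 + 0.5 * diag(6))
  colnames(x) <- paste0("v", 1:6)
  xs <- standardize_predictors(x)
  y <- as.vector(xs %*% c(0.5, -0.3, 0, 0, 0.2, 0)) + rnorm(200)
  f0 <- fit_lasso(xs, y, 0)
  ols <- coef(lm(y ~ xs))
  expect_lt(max(abs(f0$beta - ols[-1])), 1e-6)
  expect_lt(abs(f0$intercept - ols[1]), 1e-6)
  lmax <- lambda_max(xs, y)
  expect_identical(unname(fit_lasso(xs, y, lmax)$beta), rep(0, 6))
  expect_identical(unname(fit_lasso(xs, y, lmax * 2)$beta), rep(0, 6))
  expect_gt(sum(fit_lasso(xs, y, lmax * 0.95)$beta != 0), 0)
})

test_that("single standardized predictor follows the soft-threshold form", {
  set.seed(5)
  n <- 400
  x <- matrix(rnorm(n), dimnames = list(NULL, "x"))
  xs <- standardize_predictors(x)
  y <- 0.4 * as.vector(xs) + rnorm(n)
  rho <- sum(xs * (y - mean(y))) / n
  st <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (lam in c(0, 0.05, 0.2, 0.5)) {
    expect_equal(unname(fit_lasso(xs, y, lam)$beta), st(rho, lam),
                 tolerance = 1e-7)
  }
})

test_that("lasso solutions agree with glmnet across the path", {
  skip_if_not_installed("glmnet")
  set.seed(8)
  x <- matrix(rnorm(3000), 300, 10)
  x <- x %*% chol(0.4 + 0.6 * diag(10))
  colnames(x) <- paste0("m", 1:10)
  xs <- standardize_predictors(x)
  y <- as.vector(xs %*% c(-0.2, 0.2, rep(0, 8))) + rnorm(300, 0, 0.95)
  grid <- lambda_grid(xs, y)
  mine <- lasso_path(xs, y, grid)
  gl <- glmnet::glmnet(xs, y, lambda = grid, standardize = FALSE,
                       thresh = 1e-12)
  expect_lt(max(abs(mine$beta - as.matrix(gl$beta))), 1e-5)
})

test_that("lasso at zero penalty matches exhaustive OLS on 3-predictor problems", {
  set.seed(12)
  for (i in 1:5) {
    x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rnorm(100)
    for (cols in list("a", c("a", "b"), c("a", "b", "c"))) {
      sub <- x[, cols, drop = FALSE]
      expect_lt(max(abs(fit_lasso(sub, y, 0)$beta - coef(lm(y ~ sub))[-1])),
                1e-6)
    }
  }
})

test_that("cross-validated penalty selection is deterministic and recovers strong effects", {
  set.seed(30)
  x <- matrix(rnorm(3000), 300, 10, dimnames = list(NULL, paste0("m", 1:10)))
  xs <- standardize_predictors(x)
  y <- as.vector(xs %*% c(0.8, -0.8, rep(0, 8))) + rnorm(300, 0, 0.5)
  cv1 <- cross_validate_lambda(xs, y, replicates = 10, seed = 99)
  cv2 <- cross_validate_lambda(xs, y, replicates = 10, seed = 99)
  expect_identical(cv1$cv_mse, cv2$cv_mse)
  expect_identical(cv1$optimal_lambda, cv2$optimal_lambda)
  expect_true(all(c("m1", "m2") %in% cv1$nonzero_set))
  expect_identical(refit_at_lambda(xs, y, cv1$optimal_lambda), cv1$nonzero_set)
  # refit limits
  expect_length(refit_at_lambda(xs, y, lambda_max(xs, y)), 0)
  expect_length(refit_at_lambda(xs, y, 0), 10)
  expect_error(cross_validate_lambda(xs, y, grid = numeric(0)), "empty")
})

test_that("under a pure-noise response the optimum sits near lambda_max", {
  set.seed(5)
  sizes <- integer(10)
  ratios <- numeric(10)
  for (r in 1:10) {
    x <- matrix(rnorm(3000), 300, 10, dimnames = list(NULL, paste0("m", 1:10)))
    xs <- standardize_predictors(x)
    y <- as.vector(standardize_predictors(matrix(rnorm(300))))
    cv <- cross_validate_lambda(xs, y, replicates = 20, seed = r)
    sizes[r] <- length(cv$nonzero_set)
    ratios[r] <- cv$optimal_lambda / max(cv$lambda_grid)
  }
  expect_lte(median(sizes), 2)
  expect_gte(median(ratios), 0.2)
})

test_that("best-subset enumeration covers all subsets with correct statistics", {
  set.seed(61)
  x <- matrix(rnorm(150 * 6), 150, 6, dimnames = list(NULL, paste0("v", 1:6)))
  y <- x[, 3] * 0.8 + rnorm(150)
  e <- enumerate_best_subsets(x, y, rss_size = 2)
  expect_equal(nrow(e$table), 64)
  expect_equal(e$n_singular, 0)
  # spot-check AIC and adjusted R2 against lm on random subsets
  for (members in c("v3", "v1,v3", "v2,v4,v6")) {
    i <- which(e$table$members == members)
    cols <- strsplit(members, ",")[[1]]
    fit <- lm(y ~ x[, cols, drop = FALSE])
    expect_equal(e$table$aic[i], AIC(fit), tolerance = 1e-8)
    expect_equal(e$table$adj_r2[i], summary(fit)$adj.r.squared,
                 tolerance = 1e-8)
    expect_equal(e$table$rss[i], sum(resid(fit)^2), tolerance = 1e-8)
  }
  # intercept-only row
  i0 <- which(e$table$members == "")
  expect_equal(e$table$rss[i0], sum((y - mean(y))^2))
  # adjusted-R2 winner dominates the whole table
  best_adj <- max(e$table$adj_r2, na.rm = TRUE)
  expect_equal(best_adj,
               e$table$adj_r2[e$table$members ==
                                paste(e$winners$adj_r2, collapse = ",")])
  # among same-size subsets, AIC order equals RSS order
  for (k in 1:3) {
    idx <- e$table$size == k
    expect_identical(order(e$table$aic[idx]), order(e$table$rss[idx]))
  }
  # RSS weakly decreases along a nested chain
  chain <- c("", "v1", "v1,v2", "v1,v2,v3", "v1,v2,v3,v4")
  rss_chain <- e$table$rss[match(chain, e$table$members)]
  expect_true(all(diff(rss_chain) <= 1e-9))
})

test_that("a noiseless single-predictor response is found by all criteria", {
  set.seed(62)
  x <- matrix(rnorm(1000), 100, 10, dimnames = list(NULL, paste0("v", 1:10)))
  y <- 2 * x[, 3]
  e <- enumerate_best_subsets(x, y, rss_size = 1)
  expect_identical(e$winners$aic, "v3")
  expect_true("v3" %in% e$winners$adj_r2)
  expect_identical(e$winners$rss, "v3")
})

test_that("ten predictors enumerate to exactly 1024 models", {
  set.seed(63)
  x <- matrix(rnorm(100 * 10), 100, 10, dimnames = list(NULL, paste0("v", 1:10)))
  e <- enumerate_best_subsets(x, rnorm(100), rss_size = 2)
  expect_equal(nrow(e$table), 1024)
  expect_error(enumerate_best_subsets(x[1:11, ], rnorm(11)), "n > p")
})

test_that("selection intersection behaves as set intersection", {
  pair <- c("avg_bout_cadence", "avg_long_sedentary_bouts_per_day")
  r <- intersect_selections(pair, pair, pair, pair)
  expect_setequal(r$intersection, pair)
  expect_length(intersect_selections(c("a"), c("b"), c("c"), c("d"))$intersection, 0)
  expect_length(intersect_selections(character(0), pair, pair, pair)$intersection, 0)
  r2 <- intersect_selections(c("a", "b", "c"), c("b", "c"), c("b"), c("b", "d"))
  expect_identical(r2$intersection, "b")
})

test_that("the coefficient path is continuous on a fine grid", {
  set.seed(64)
  x <- matrix(rnorm(2000), 200, 10, dimnames = list(NULL, paste0("m", 1:10)))
  xs <- standardize_predictors(x)
  y <- as.vector(xs %*% c(0.4, -0.4, rep(0, 8))) + rnorm(200, 0, 0.8)
  coarse <- lasso_path(xs, y, lambda_grid(xs, y, length = 50))
  fine <- lasso_path(xs, y, lambda_grid(xs, y, length = 400))
  jump <- function(B) max(abs(B[, -1] - B[, -ncol(B)]))
  expect_lt(jump(fine$beta), jump(coarse$beta) / 2)
})
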