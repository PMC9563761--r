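#' Standardize predictor columns
#'
#' Column-wise `(x - mean) / sd` using the population SD convention
#' (denominator `n`), so `c(1, 2, 3)` maps to `c(-1.2247, 0, 1.2247)`. The
#' centers and scales are attached as attributes for back-transformation.
#'
#' @param x numeric matrix or data frame.
#' @return Standardized matrix with attributes `center` and `scale`.
#' @export
standardize_predictors <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  if (any(scl == 0)) {
    stop("constant column(s) cannot be standardized: ",
         paste(colnames(x)[scl == 0], collapse = ", "))
  }
  out <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

# Population-SD standardization of a vector.
standardize_response <- function(y) {
  s <- sqrt(mean((y - mean(y))^2))
  if (s == 0) stop("response is constant")
  structure((y - mean(y)) / s, center = mean(y), scale = s)
}

#' Smallest penalty with an all-zero lasso solution
#'
#' For the objective `(1/(2n)) * sum((y - b0 - X beta)^2) + lambda * sum(|beta|)`
#' all slopes are exactly zero once `lambda >= max_j |x_j' y| / n` (columns
#' and response mean-centered).
#'
#' @param x predictor matrix.
#' @param y response vector.
#' @return The penalty bound `lambda_max`.
#' @export
lambda_max <- function(x, y) {
  x <- as.matrix(x)
  xc <- sweep(x, 2, colMeans(x))
  yc <- y - mean(y)
  max(abs(crossprod(xc, yc))) / nrow(x)
}

#' Log-spaced penalty grid
#'
#' `length` penalties descending log-linearly from [lambda_max()] down to
#' `lambda_max * min_ratio`.
#'
#' @inheritParams lambda_max
#' @param length grid size (default 100).
#' @param min_ratio smallest penalty as a fraction of `lambda_max`
#'   (default 1e-4).
#' @return Descending numeric vector of penalties.
#' @export
lambda_grid <- function(x, y, length = 100L, min_ratio = 1e-4) {
  lmax <- lambda_max(x, y)
  if (lmax == 0) lmax <- 1e-3   # degenerate: response uncorrelated with all columns
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = length))
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# Coordinate descent at a single penalty, via the compiled path kernel.
lasso_cd <- function(XtX, Xty, beta, lambda, tol, max_iter) {
  fit <- .lasso_cd_path(XtX, Xty, lambda, beta, tol, as.integer(max_iter))
  list(beta = as.vector(fit$beta), iterations = fit$iterations[1L])
}

#' Fit the lasso at a fixed penalty
#'
#' Minimizes `(1/(2n)) * sum((y - b0 - X beta)^2) + lambda * sum(|beta|)` by
#' cyclic coordinate descent with an unpenalized intercept (columns and
#' response are mean-centered internally). At `lambda = 0` the solution is
#' the least-squares fit; at `lambda >= lambda_max(x, y)` all slopes are
#' exactly zero.
#'
#' @param x predictor matrix (any scaling; standardize first for penalty
#'   comparability across predictors).
#' @param y response vector.
#' @param lambda penalty, `>= 0`.
#' @param tol convergence tolerance on the maximum coefficient change per
#'   sweep, relative to the largest coefficient magnitude once that exceeds
#'   one (default 1e-7).
#' @param max_iter sweep cap (default 1e5); exceeding it is an error.
#' @return A list of class `walkbp_lasso`: `intercept`, `beta` (named),
#'   `lambda`, `iterations`.
#' @export
fit_lasso <- function(x, y, lambda, tol = 1e-7, max_iter = 1e5) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  n <- nrow(x)
  if (length(y) != n) stop("x and y dimensions disagree")
  if (lambda < 0) stop("lambda must be >= 0")
  xm <- colMeans(x)
  xc <- sweep(x, 2, xm)
  ym <- mean(y)
  XtX <- crossprod(xc) / n
  Xty <- crossprod(xc, y - ym) / n
  fit <- lasso_cd(XtX, as.vector(Xty), numeric(ncol(x)), lambda, tol, max_iter)
  beta <- setNames(fit$beta, colnames(x))
  structure(
    list(intercept = ym - sum(xm * beta), beta = beta, lambda = lambda,
         iterations = fit$iterations),
    class = "walkbp_lasso"
  )
}

# Warm-started path over a descending penalty grid; returns p x L coefficient
# matrix (slopes only) plus intercepts.
lasso_path <- function(x, y, lambdas, tol = 1e-7, max_iter = 1e5) {
  x <- as.matrix(x)
  n <- nrow(x)
  xm <- colMeans(x)
  xc <- sweep(x, 2, xm)
  ym <- mean(y)
  XtX <- crossprod(xc) / n
  Xty <- as.vector(crossprod(xc, y - ym) / n)
  p <- ncol(x)
  fit <- .lasso_cd_path(XtX, Xty, lambdas, numeric(p), tol, as.integer(max_iter))
  B <- fit$beta
  dimnames(B) <- list(colnames(x), NULL)
  list(beta = B, intercept = ym - as.vector(xm %*% B), lambda = lambdas)
}

#' Choose the lasso penalty by replicated cross-validation
#'
#' K-fold cross-validation of the test mean squared error over a descending
#' penalty grid, replicated with fresh random fold partitions and averaged
#' (folds first, then replicates). The optimal penalty is the arg-min of the
#' averaged curve, with ties broken toward the larger penalty (sparser
#' model). The lasso is then refit on all data at the optimal penalty and the
#' predictors with nonzero coefficients reported.
#'
#' @param x standardized predictor matrix.
#' @param y (standardized) response.
#' @param folds number of folds (default 10).
#' @param replicates number of independent fold partitions (default 100).
#' @param grid descending penalty grid; `NULL` (default) uses
#'   [lambda_grid()] of size `grid_size` down to `grid_min_ratio`.
#' @param seed seed for the fold partitions.
#' @param grid_size,grid_min_ratio grid construction when `grid` is `NULL`.
#' @return A list of class `lasso_cv`: `lambda_grid`, `cv_mse` (averaged
#'   curve), `optimal_lambda`, `refit` (full-data [fit_lasso()] at the
#'   optimum), `nonzero_set`, `folds`, `replicates`.
#' @export
cross_validate_lambda <- function(x, y, folds = 10L, replicates = 100L,
                                  grid = NULL, seed = NULL,
                                  grid_size = 100L, grid_min_ratio = 1e-4) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < folds) stop("need at least as many observations as folds")
  if (is.null(grid)) grid <- lambda_grid(x, y, grid_size, grid_min_ratio)
  if (length(grid) == 0L) stop("penalty grid is empty")
  if (is.unsorted(rev(grid))) stop("penalty grid must be descending")
  L <- length(grid)
  with_seed(seed, {
    acc <- numeric(L)
    for (r in seq_len(replicates)) {
      foldid <- sample(rep_len(seq_len(folds), n))
      fold_mse <- matrix(0, folds, L)
      for (k in seq_len(folds)) {
        te <- foldid == k
        path <- lasso_path(x[!te, , drop = FALSE], y[!te], grid)
        pred <- x[te, , drop = FALSE] %*% path$beta +
          rep(path$intercept, each = sum(te))
        fold_mse[k, ] <- colMeans((y[te] - pred)^2)
      }
      acc <- acc + colMeans(fold_mse)
    }
    cv_mse <- acc / replicates
    opt <- grid[which.min(cv_mse)]   # descending grid: first min = largest lambda
    refit <- fit_lasso(x, y, opt)
    structure(
      list(lambda_grid = grid, cv_mse = cv_mse, optimal_lambda = opt,
           refit = refit,
           nonzero_set = names(refit$beta)[abs(refit$beta) > 0],
           folds = folds, replicates = replicates),
      class = "lasso_cv"
    )
  })
}

#' @export
print.lasso_cv <- function(x, ...) {
  cat(sprintf("Lasso %d-fold CV x %d replicates over %d penalties\n",
              x$folds, x$replicates, length(x$lambda_grid)))
  cat(sprintf("  optimal lambda %.5g (CV MSE %.4f)\n",
              x$optimal_lambda, min(x$cv_mse)))
  cat("  nonzero at optimum:",
      if (length(x$nonzero_set)) paste(x$nonzero_set, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

#' Refit the lasso on all data and report the selected set
#'
#' @inheritParams fit_lasso
#' @param lambda the cross-validated optimal penalty.
#' @return Character vector of predictors with nonzero coefficients.
#' @export
refit_at_lambda <- function(x, y, lambda) {
  fit <- fit_lasso(x, y, lambda)
  names(fit$beta)[abs(fit$beta) > 0]
}
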