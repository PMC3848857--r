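#' @name elastic_net_solver
#' @title Penalized regression of a gene signature on miRNA influence
#'
#' @description
#' The enrichment model regresses the 0/1 signature membership vector y on
#' the gene-by-miRNA influence matrix X, minimizing
#' \deqn{\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i\beta)^2 +
#'       \lambda \sum_j \left[\tfrac{1}{2}(1-\alpha)\beta_j^2 +
#'       \alpha|\beta_j|\right]}
#' the elastic-net objective in the glmnet scaling, so \eqn{\lambda} values
#' are directly comparable with that ecosystem. \eqn{\alpha = 1} is the
#' lasso, \eqn{\alpha = 0} ridge; intermediate values spread weight over
#' correlated miRNA-family columns while still producing sparse solutions.
#' The intercept is never penalized. Fitting is cyclic coordinate descent
#' with covariance updates, warm-started along a log-spaced \eqn{\lambda}
#' path; \eqn{\lambda} is selected by k-fold cross-validation at minimum
#' mean squared error and \eqn{\alpha} either fixed (default 0.6) or chosen
#' by the stabilization rule of [optimize_alpha()].
NULL

#' Regression configuration
#'
#' @param alpha Elastic-net mixing parameter in \[0, 1\], or `"auto"` to run
#'   the [optimize_alpha()] grid search. Default 0.6, the value at which the
#'   cross-validated `lambda_min` stabilizes on this class of designs.
#' @param alpha_grid Grid used when `alpha = "auto"`: 20 evenly spaced
#'   values from 0 to 1.
#' @param n_lambda Number of path penalties (default 100).
#' @param lambda_min_ratio Smallest path penalty as a fraction of
#'   `lambda_max` (default 1e-4).
#' @param n_folds Cross-validation folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param standardize Scale predictor columns to unit (population) variance
#'   before fitting; coefficients are reported on the original scale either
#'   way. Default `TRUE`.
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change per sweep (default 1e-7).
#' @param max_iter Maximum coordinate-descent sweeps per penalty
#'   (default 10000).
#' @param stability_tol Relative `lambda_min` change below which consecutive
#'   grid alphas count as stable (default 0.05).
#' @return A `regression_config` list.
#' @export
regression_config <- function(alpha = 0.6,
                              alpha_grid = seq(0, 1, length.out = 20),
                              n_lambda = 100L,
                              lambda_min_ratio = 1e-4,
                              n_folds = 10L,
                              seed = 1L,
                              standardize = TRUE,
                              tol = 1e-7,
                              max_iter = 10000L,
                              stability_tol = 0.05) {
  if (!identical(alpha, "auto")) {
    stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  }
  stopifnot(!is.unsorted(alpha_grid), all(alpha_grid >= 0), all(alpha_grid <= 1),
            n_lambda >= 2L, lambda_min_ratio > 0, lambda_min_ratio < 1,
            n_folds >= 2L, tol > 0, max_iter >= 1L, stability_tol > 0)
  structure(list(alpha = alpha, alpha_grid = alpha_grid,
                 n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 standardize = isTRUE(standardize), tol = tol,
                 max_iter = as.integer(max_iter),
                 stability_tol = stability_tol),
            class = "regression_config")
}

#' Soft-thresholding operator
#'
#' `sign(z) * max(|z| - gamma, 0)`, the proximal map of the absolute-value
#' penalty and the kernel of every lasso coordinate update.
#'
#' @param z Numeric vector.
#' @param gamma Threshold, `>= 0`.
#' @return Thresholded values.
#' @export
soft_threshold <- function(z, gamma) {
  stopifnot(all(gamma >= 0))
  sign(z) * pmax(abs(z) - gamma, 0)
}

# Centering/scaling bookkeeping shared by the solver entry points.
# Population (1/n) standard deviation, matching the glmnet convention.
standardize_design <- function(X, y, standardize) {
  n <- nrow(X)
  x_mean <- colMeans(X)
  Xc <- sweep(X, 2L, x_mean, "-")
  x_scale <- if (standardize) sqrt(colSums(Xc^2) / n) else rep(1, ncol(X))
  constant <- x_scale == 0 | colSums(Xc^2) == 0
  x_scale[constant | x_scale == 0] <- 1
  Xs <- sweep(Xc, 2L, x_scale, "/")
  y_mean <- mean(y)
  list(Xs = Xs, yc = y - y_mean, x_mean = x_mean, x_scale = x_scale,
       y_mean = y_mean, constant = constant)
}

# Path fit on prepared inputs; returns original-scale coefficients.
enet_path <- function(X, y, lambdas, alpha, config = regression_config(),
                      warm_start = NULL, trace_objective = FALSE) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite values in X or y")
  }
  if (nrow(X) != length(y)) stop("dimension mismatch: nrow(X) != length(y)")
  if (nrow(X) < 2L || ncol(X) < 1L) stop("need n >= 2 and p >= 1")
  stopifnot(all(lambdas >= 0), !is.unsorted(rev(lambdas)))
  n <- nrow(X); p <- ncol(X)
  std <- standardize_design(X, y, config$standardize)
  if (any(std$constant)) {
    warning(sprintf("dropping %d constant column(s) before fitting",
                    sum(std$constant)))
  }
  keep <- !std$constant
  Xs <- std$Xs[, keep, drop = FALSE]
  XtX <- crossprod(Xs)
  Xty <- drop(crossprod(Xs, std$yc))
  yty <- sum(std$yc^2)
  ws <- NULL
  if (!is.null(warm_start)) {
    stopifnot(length(warm_start) == p)
    ws <- (warm_start * std$x_scale)[keep]
  }
  fit <- .cd_path(XtX, Xty, yty, n, as.numeric(lambdas), alpha,
                  config$tol, config$max_iter, ws, trace_objective)
  beta <- matrix(0, p, length(lambdas),
                 dimnames = list(colnames(X), NULL))
  beta[keep, ] <- fit$beta / std$x_scale[keep]
  intercept <- std$y_mean - drop(crossprod(std$x_mean, beta))
  out <- list(beta = beta, intercept = intercept, lambdas = lambdas,
              alpha = alpha, n_iter = fit$n_iter, converged = fit$converged)
  if (trace_objective) out$objective_trace <- fit$objective_trace
  out
}

#' Fit the elastic net at a single penalty by coordinate descent
#'
#' Cyclic coordinate descent with covariance updates on the standardized
#' design; coefficients are returned on the original predictor scale and the
#' unpenalized intercept is recovered from the column means.
#'
#' @param X Numeric n-by-p predictor matrix. Constant columns are dropped
#'   with a warning (their coefficient is 0).
#' @param y Numeric response of length n.
#' @param lambda Penalty strength, `>= 0`.
#' @param alpha Mixing parameter in \[0, 1\].
#' @param config A [regression_config()].
#' @param warm_start Optional coefficient vector (original scale) to start
#'   from.
#' @return A `fit_result`: `beta` (named), `intercept`, `lambda`, `alpha`,
#'   `n_iter`, `converged`. Non-convergence raises a warning.
#' @export
coordinate_descent <- function(X, y, lambda, alpha,
                               config = regression_config(),
                               warm_start = NULL) {
  stopifnot(length(lambda) == 1L, lambda >= 0,
            length(alpha) == 1L, alpha >= 0, alpha <= 1)
  path <- enet_path(X, y, lambda, alpha, config, warm_start)
  if (!path$converged[1L]) {
    warning(sprintf("coordinate descent did not converge in %d sweeps (lambda=%g, alpha=%g)",
                    config$max_iter, lambda, alpha))
  }
  structure(list(beta = path$beta[, 1L], intercept = path$intercept[1L],
                 lambda = lambda, alpha = alpha,
                 n_iter = path$n_iter[1L], converged = path$converged[1L]),
            class = "fit_result")
}

#' Smallest penalty that zeroes all coefficients
#'
#' `max_j |<x_j, y - mean(y)>| / (n * max(alpha, 0.001))` on the design as
#' configured (standardized when `standardize` is on). The 0.001 floor keeps
#' the path anchor finite as `alpha` approaches ridge.
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param alpha Mixing parameter.
#' @param standardize Standardize columns first (default `TRUE`).
#' @return The path anchor `lambda_max`.
#' @export
compute_lambda_max <- function(X, y, alpha, standardize = TRUE) {
  X <- as.matrix(X)
  yc <- y - mean(y)
  if (all(yc == 0)) stop("degenerate response")
  Xw <- if (standardize) standardize_design(X, y, TRUE)$Xs else X
  max(abs(drop(crossprod(Xw, yc)))) / (nrow(X) * max(alpha, 0.001))
}

#' Log-spaced penalty path
#'
#' @param lambda_max Path anchor (first, largest value).
#' @param n_lambda Number of values (default 100).
#' @param ratio Smallest value as a fraction of `lambda_max`
#'   (default 1e-4).
#' @return Strictly decreasing sequence from `lambda_max` to
#'   `lambda_max * ratio`, log-spaced, inclusive of both ends.
#' @export
lambda_path <- function(lambda_max, n_lambda = 100L, ratio = 1e-4) {
  stopifnot(lambda_max > 0, n_lambda >= 2L, ratio > 0, ratio < 1)
  exp(seq(log(lambda_max), log(lambda_max * ratio), length.out = n_lambda))
}

#' Stratified cross-validation fold assignment
#'
#' Folds are stratified by response class (signature members vs
#' non-members) so every training split retains positives; assignment is a
#' deterministic function of `y`, `n_folds` and `seed`.
#'
#' @param y Response vector (binary stratification when it has two unique
#'   values; plain shuffling otherwise).
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id (1..n_folds) per observation.
#' @export
make_folds <- function(y, n_folds, seed) {
  n <- length(y)
  stopifnot(n >= n_folds)
  folds <- integer(n)
  with_seed(seed, {
    if (length(unique(y)) <= 2L) {
      for (cls in unique(sort(y))) {
        idx <- which(y == cls)
        idx <- idx[sample.int(length(idx))]
        folds[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      folds[sample.int(n)] <- rep_len(seq_len(n_folds), n)
    }
  })
  folds
}

#' k-fold cross-validation over a penalty path
#'
#' Fits a warm-started path per training fold and scores held-out squared
#' error per penalty. `lambda_min` is the penalty with minimum mean MSE;
#' exact ties resolve to the larger penalty (the sparser model). Folds whose
#' training response is constant are skipped with a warning; more than half
#' skipped is an error.
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param alpha Mixing parameter.
#' @param lambdas Decreasing penalty sequence; computed from
#'   [compute_lambda_max()] and [lambda_path()] when `NULL`.
#' @param n_folds Number of folds (default from `config`).
#' @param seed Fold seed (default from `config`).
#' @param config A [regression_config()].
#' @return A `cv_curve`: `lambdas`, `mean_mse`, `sd_mse` (across folds),
#'   `lambda_min`, `alpha`, `n_folds_used`.
#' @export
kfold_cv <- function(X, y, alpha, lambdas = NULL,
                     n_folds = config$n_folds, seed = config$seed,
                     config = regression_config()) {
  X <- as.matrix(X)
  if (is.null(lambdas)) {
    lmax <- compute_lambda_max(X, y, alpha, config$standardize)
    lambdas <- lambda_path(lmax, config$n_lambda, config$lambda_min_ratio)
  }
  folds <- make_folds(y, n_folds, seed)
  fold_mse <- matrix(NA_real_, n_folds, length(lambdas))
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    if (length(unique(y[tr])) < 2L) {
      warning(sprintf("fold %d skipped: constant training response", k))
      next
    }
    fit <- enet_path(X[tr, , drop = FALSE], y[tr], lambdas, alpha, config)
    pred <- X[!tr, , drop = FALSE] %*% fit$beta
    pred <- sweep(pred, 2L, fit$intercept, "+")
    fold_mse[k, ] <- colMeans((y[!tr] - pred)^2)
  }
  used <- !is.na(fold_mse[, 1L])
  if (sum(used) < n_folds / 2) {
    stop("more than half of the cross-validation folds were skipped")
  }
  mean_mse <- colMeans(fold_mse[used, , drop = FALSE])
  sd_mse <- apply(fold_mse[used, , drop = FALSE], 2L, stats::sd)
  i_min <- which(mean_mse == min(mean_mse))[1L]  # lambdas descending
  structure(list(lambdas = lambdas, mean_mse = mean_mse, sd_mse = sd_mse,
                 lambda_min = lambdas[i_min], alpha = alpha,
                 n_folds_used = sum(used)),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(sprintf("<cv_curve> alpha=%g, %d lambdas, lambda_min=%.6g (mean MSE %.6g)\n",
              x$alpha, length(x$lambdas), x$lambda_min, min(x$mean_mse)))
  invisible(x)
}

#' Write cross-validation diagnostics as TSV
#'
#' @param cv A `cv_curve`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cv_curve <- function(cv, path) {
  stopifnot(inherits(cv, "cv_curve"))
  write_table(data.frame(alpha = cv$alpha, lambda = cv$lambdas,
                         mean_mse = cv$mean_mse, sd_mse = cv$sd_mse), path)
}

#' Stabilization rule for the mixing parameter
#'
#' Given per-alpha cross-validated `lambda_min` values on an ascending grid,
#' selects the smallest alpha from which `lambda_min` stays stable: every
#' consecutive pair of later grid points changes by less than
#' `stability_tol` in relative terms. Single-element grids return their
#' element; if no alpha qualifies the conventional 0.6 is returned with a
#' warning.
#'
#' @param alphas Ascending alpha grid.
#' @param lambda_mins `lambda_min` per alpha.
#' @param stability_tol Relative-change threshold (default 0.05).
#' @return The selected alpha.
#' @export
select_stable_alpha <- function(alphas, lambda_mins, stability_tol = 0.05) {
  stopifnot(length(alphas) == length(lambda_mins), length(alphas) >= 1L,
            !is.unsorted(alphas))
  K <- length(alphas)
  if (K == 1L) return(alphas[1L])
  rel <- abs(diff(lambda_mins)) / lambda_mins[-K]
  stable_pair <- rel < stability_tol
  for (i in seq_len(K - 1L)) {
    if (all(stable_pair[i:(K - 1L)])) return(alphas[i])
  }
  warning("lambda_min never stabilizes on the alpha grid; falling back to alpha = 0.6")
  0.6
}

#' Select the mixing parameter by lambda-min stabilization
#'
#' Runs [kfold_cv()] for every grid alpha (each with its own penalty path)
#' and applies [select_stable_alpha()] to the resulting `lambda_min`
#' profile.
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param config A [regression_config()]; the grid is
#'   `config$alpha_grid`.
#' @return List with `alpha_star` and `table` (data frame of `alpha`,
#'   `lambda_min`, `min_mean_mse`).
#' @export
optimize_alpha <- function(X, y, config = regression_config()) {
  grid <- config$alpha_grid
  lambda_mins <- numeric(length(grid))
  min_mse <- numeric(length(grid))
  for (i in seq_along(grid)) {
    cv <- kfold_cv(X, y, grid[i], config = config)
    lambda_mins[i] <- cv$lambda_min
    min_mse[i] <- min(cv$mean_mse)
  }
  alpha_star <- select_stable_alpha(grid, lambda_mins, config$stability_tol)
  list(alpha_star = alpha_star,
       table = data.frame(alpha = grid, lambda_min = lambda_mins,
                          min_mean_mse = min_mse))
}
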