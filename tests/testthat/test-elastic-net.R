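test_that("soft thresholding shrinks toward zero and is identity at zero threshold", {
  expect_equal(soft_threshold(3.0, 1.0), 2.0)
  expect_equal(soft_threshold(-0.5, 1.0), 0.0)
  z <- c(-2.5, -0.1, 0, 0.1, 2.5)
  expect_equal(soft_threshold(z, 0), z)
  expect_equal(soft_threshold(-3, 1), -2)
  expect_error(soft_threshold(1, -0.1))
})

test_that("lambda_max is the smallest penalty that zeroes the lasso solution", {
  X <- matrix(c(1, -1), 2, 1)
  y <- c(1, -1)
  expect_equal(compute_lambda_max(X, y, 1, standardize = FALSE), 1.0)
  expect_equal(compute_lambda_max(X, 2 * y, 1, standardize = FALSE), 2.0)

  inst <- random_instance(7, n = 40, p = 6)
  lmax <- compute_lambda_max(inst$X, inst$y, 1)
  at <- coordinate_descent(inst$X, inst$y, lmax, 1)
  expect_true(all(at$beta == 0))
  below <- coordinate_descent(inst$X, inst$y, 0.99 * lmax, 1)
  expect_gte(sum(below$beta != 0), 1L)
  expect_error(compute_lambda_max(inst$X, rep(2, 40), 1),
               "degenerate response")
})

test_that("lambda path is log-spaced, decreasing and endpoint-inclusive", {
  expect_equal(lambda_path(1.0, 3, 0.01), c(1.0, 0.1, 0.01))
  p <- lambda_path(2.5, 100, 1e-4)
  expect_equal(p[1], 2.5)
  expect_equal(p[100], 2.5e-4)
  expect_true(all(diff(p) < 0))
  expect_equal(length(p), 100L)
})

test_that("unpenalized fit reproduces ordinary least squares", {
  inst <- random_instance(11, n = 50, p = 5)
  fit <- coordinate_descent(inst$X, inst$y, 0, 0.6,
                            regression_config(tol = 1e-12))
  ols <- stats::lm(inst$y ~ inst$X)
  expect_equal(unname(fit$beta), unname(coef(ols)[-1]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-6)
})

test_that("ridge solution matches the closed form on centered data", {
  for (seed in c(3, 17)) {
    inst <- random_instance(seed, n = 40, p = 6)
    lambda <- 0.3
    cfg <- regression_config(standardize = FALSE, tol = 1e-12,
                             max_iter = 100000)
    fit <- coordinate_descent(inst$X, inst$y, lambda, 0, cfg)
    Xc <- scale(inst$X, scale = FALSE)
    yc <- inst$y - mean(inst$y)
    n <- nrow(Xc)
    closed <- solve(crossprod(Xc) / n + lambda * diag(ncol(Xc)),
                    crossprod(Xc, yc) / n)
    expect_equal(unname(fit$beta), drop(closed), tolerance = 1e-6)
  }
})

test_that("coordinate descent agrees with a high-precision proximal-gradient oracle", {
  combos <- expand.grid(alpha = c(0, 0.6, 1), lambda = c(0.02, 0.1))
  for (i in seq_len(nrow(combos))) {
    inst <- random_instance(100 + i, n = 30, p = 8)
    a <- combos$alpha[i]; l <- combos$lambda[i]
    cfg <- regression_config(standardize = FALSE, tol = 1e-11,
                             max_iter = 100000)
    fit <- coordinate_descent(inst$X, inst$y, l, a, cfg)
    oracle <- fista_enet(inst$X, inst$y, l, a)
    obj_fit <- enet_objective(inst$X, inst$y, fit$intercept, fit$beta, l, a)
    obj_orc <- enet_objective(inst$X, inst$y, oracle$intercept, oracle$beta,
                              l, a)
    expect_lt(abs(obj_fit - obj_orc), 1e-6)
    expect_lt(max(abs(fit$beta - oracle$beta)), 1e-4)
  }
})

test_that("solver agrees with glmnet on the lasso objective", {
  # cross-check restricted to alpha = 1: for 0 < alpha < 1 glmnet's internal
  # response standardization rescales the ridge part of the penalty, so its
  # solutions answer a slightly different objective than the one stated here
  skip_if_not_installed("glmnet")
  for (seed in c(42, 43)) {
    inst <- random_instance(seed, n = 60, p = 10)
    lam <- 0.05
    g <- glmnet::glmnet(inst$X, inst$y, alpha = 1, lambda = lam,
                        standardize = TRUE, thresh = 1e-14)
    fit <- coordinate_descent(inst$X, inst$y, lam, 1,
                              regression_config(tol = 1e-12,
                                                max_iter = 200000))
    gb <- as.numeric(glmnet::coef.glmnet(g))
    expect_equal(unname(fit$beta), gb[-1], tolerance = 1e-4)
    expect_equal(fit$intercept, gb[1], tolerance = 1e-4)
  }
})

test_that("the objective never increases across coordinate-descent sweeps", {
  for (seed in c(5, 23)) {
    inst <- random_instance(seed, n = 30, p = 10)
    path <- mircontext:::enet_path(inst$X, inst$y, c(0.2, 0.05), 0.6,
                                   regression_config(standardize = FALSE),
                                   trace_objective = TRUE)
    for (tr in path$objective_trace) {
      expect_true(all(diff(tr) <= 1e-12))
    }
  }
})

test_that("lasso path sparsity is monotone in the penalty", {
  for (seed in 1:5) {
    inst <- random_instance(seed, n = 40, p = 15)
    lmax <- compute_lambda_max(inst$X, inst$y, 1)
    lams <- lambda_path(lmax, 30, 1e-3)
    path <- mircontext:::enet_path(inst$X, inst$y, lams, 1,
                                   regression_config())
    nnz <- colSums(path$beta != 0)
    # support growth is monotone up to rare single excursions where a
    # variable leaves the active set as the penalty decreases
    drops <- rle(diff(nnz) < 0)
    excursions <- sum(drops$values)
    expect_lte(excursions, 1L)
  }
})

test_that("constant predictor columns are dropped with a warning and zero coefficient", {
  inst <- random_instance(9, n = 30, p = 4)
  X <- cbind(inst$X, const = 5)
  expect_warning(fit <- coordinate_descent(X, inst$y, 0.05, 0.6),
                 "constant column")
  expect_equal(unname(fit$beta[5]), 0)
  expect_error(coordinate_descent(X[1:10, ], inst$y, 0.05, 0.6),
               "dimension mismatch")
  X[1, 1] <- NA
  expect_error(coordinate_descent(X, inst$y, 0.05, 0.6), "non-finite")
})

test_that("stratified folds are deterministic and keep positives in every fold", {
  y <- rep(c(0, 1), c(80, 20))
  f1 <- make_folds(y, 10, seed = 3)
  f2 <- make_folds(y, 10, seed = 3)
  expect_identical(f1, f2)
  expect_false(identical(f1, make_folds(y, 10, seed = 4)))
  per_fold_pos <- tapply(y, f1, sum)
  expect_true(all(per_fold_pos == 2))
})

test_that("cross-validation is deterministic and selects an in-path penalty", {
  inst <- random_instance(21, n = 50, p = 8)
  cfg <- regression_config(n_lambda = 20)
  cv1 <- kfold_cv(inst$X, inst$y, 0.6, n_folds = 5, seed = 2, config = cfg)
  cv2 <- kfold_cv(inst$X, inst$y, 0.6, n_folds = 5, seed = 2, config = cfg)
  expect_identical(cv1$mean_mse, cv2$mean_mse)
  expect_identical(cv1$lambda_min, cv2$lambda_min)
  expect_true(cv1$lambda_min %in% cv1$lambdas)
  expect_equal(length(cv1$mean_mse), length(cv1$lambdas))
  expect_equal(min(cv1$mean_mse),
               cv1$mean_mse[which(cv1$lambdas == cv1$lambda_min)])
})

test_that("fold MSEs match per-fold least-squares oracles at negligible penalty", {
  set.seed(4)
  X <- matrix(rnorm(12), 12, 1)
  y <- drop(2 * X) + rnorm(12, sd = 0.1)
  lams <- c(1e-6, 1e-8)
  cv <- kfold_cv(X, y, 1, lambdas = lams, n_folds = 2, seed = 5)
  folds <- make_folds(y, 2, seed = 5)
  fold_mse <- vapply(1:2, function(k) {
    tr <- folds != k
    m <- stats::lm(y[tr] ~ X[tr, 1])
    pred <- coef(m)[1] + coef(m)[2] * X[!tr, 1]
    mean((y[!tr] - pred)^2)
  }, numeric(1))
  expect_equal(cv$mean_mse[2], mean(fold_mse), tolerance = 1e-4)
  expect_equal(cv$sd_mse[2], sd(fold_mse), tolerance = 1e-4)
})

test_that("cross-validation skips folds with constant training response", {
  set.seed(8)
  # a single positive: the fold holding it trains on all zeros and is skipped
  y <- c(rep(0, 10), 1)
  X <- matrix(rnorm(22), 11, 2)
  expect_warning(
    cv <- kfold_cv(X, y, 0.6, lambdas = c(0.1, 0.01), n_folds = 2, seed = 1),
    "constant training response")
  expect_equal(cv$n_folds_used, 1L)
  # constant response everywhere: every fold skipped, which is an error
  suppressWarnings(
    expect_error(kfold_cv(X, rep(0, 11), 0.6, lambdas = c(0.1, 0.01),
                          n_folds = 2, seed = 1),
                 "more than half"))
})

test_that("alpha stabilization picks the first stable grid point with 0.6 fallback", {
  alphas <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  expect_equal(select_stable_alpha(alphas, c(5.0, 2.0, 1.00, 1.01, 1.00)), 0.6)
  expect_warning(
    out <- select_stable_alpha(alphas, c(16, 8, 4, 2, 1)),
    "never stabilizes")
  expect_equal(out, 0.6)
  expect_equal(select_stable_alpha(0.3, 2.2), 0.3)
})

test_that("alpha grid search returns a per-alpha lambda table and a grid alpha", {
  inst <- random_instance(31, n = 40, p = 5)
  cfg <- regression_config(alpha = "auto", alpha_grid = c(0.2, 0.6, 1),
                           n_lambda = 15, n_folds = 4, seed = 1)
  opt <- suppressWarnings(optimize_alpha(inst$X, inst$y, cfg))
  expect_equal(nrow(opt$table), 3L)
  expect_true(all(opt$table$lambda_min > 0))
  expect_true(opt$alpha_star %in% c(cfg$alpha_grid, 0.6))
})
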