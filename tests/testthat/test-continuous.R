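test_that("OLS reproduces closed-form solutions", {
  f <- fit_ols(matrix(c(0, 1, 2)), c(1, 2, 4))
  expect_equal(unname(f$coefficients), 1.5)
  expect_equal(f$intercept, 5 / 6)      # ybar - slope * xbar = 7/3 - 3/2
  # intercept-only model returns the mean
  f0 <- fit_ols(matrix(nrow = 4, ncol = 0), c(1, 2, 3, 10))
  expect_equal(f0$intercept, 4)
  # exact linear relationship -> zero residuals
  x <- rand_design(20, 2, 1)
  y <- 2 + 3 * x[, 1] - x[, 2]
  fe <- fit_ols(x, y)
  expect_equal(max(abs(y - predict(fe, x))), 0, tolerance = 1e-10)
  # rank deficiency -> minimum-norm solution, flagged
  xd <- cbind(x, x[, 1])
  expect_warning(fd <- fit_ols(xd, y), "minimum-norm")
  expect_true(fd$rank_deficient)
})

test_that("lasso limits: OLS at zero, null model beyond lambda_max", {
  x <- rand_design(60, 5, 2)
  y <- drop(x %*% c(2, -1, 0, 0, 0.5)) + rnorm(60)
  f0 <- fit_lasso(x, y, 0)
  fo <- fit_ols(x, y)
  expect_lt(max(abs(f0$coefficients - fo$coefficients)), 1e-6)
  expect_lt(abs(f0$intercept - fo$intercept), 1e-6)
  fz <- fit_lasso(x, y, f0$lambda_max * (1 + 1e-9))
  expect_true(all(fz$coefficients == 0))
  expect_equal(fz$intercept, mean(y))
})

test_that("single standardized predictor matches the soft threshold", {
  set.seed(3)
  x <- rnorm(50)
  xs <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))  # population scaling
  y <- 1.3 * xs + rnorm(50, sd = 0.4)
  b <- mean(xs * (y - mean(y)))                      # univariate OLS slope
  for (lam in c(0.1, 0.4, 0.8)) {
    f <- fit_lasso(matrix(xs), y, lam)
    expected <- if (lam < abs(b)) sign(b) * (abs(b) - lam) else 0
    expect_equal(unname(f$coefficients), expected, tolerance = 1e-8)
  }
})

test_that("orthonormal designs follow the soft-threshold path exactly", {
  set.seed(4)
  n <- 64; p <- 4
  # columns orthonormal and orthogonal to the intercept, then scaled so the
  # population SD is exactly 1: the standardized Gram is the identity
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))[, -1] * sqrt(n)
  y <- drop(Q %*% c(1.5, -0.8, 0.3, 0)) + rnorm(n, sd = 0.3)
  bj <- colMeans(Q * (y - mean(y)))
  stopifnot(max(abs(crossprod(Q) / n - diag(p))) < 1e-8)
  for (lam in c(0.05, 0.3, 0.7, 1.2)) {
    f <- fit_lasso(Q, y, lam)
    beta_std <- sign(bj) * pmax(abs(bj) - lam, 0)
    expect_equal(unname(f$coefficients), unname(beta_std),
                 tolerance = 1e-8)
  }
})

test_that("coordinate-descent objective is monotone non-increasing", {
  x <- rand_design(80, 8, 5)
  y <- signal_outcome(x, 0.6, 5)
  f <- fit_lasso(x, y, 0.2, trace_objective = TRUE)
  tr <- f$objective_trace
  expect_gt(length(tr), 1)
  expect_true(all(diff(tr) <= 1e-12))
})

test_that("lasso agrees with an independent solver", {
  skip_if_not_installed("glmnet")
  x <- rand_design(70, 6, 6)
  y <- signal_outcome(x, 0.5, 6)
  for (lam in c(0.05, 0.2, 0.6)) {
    ours <- fit_lasso(x, y, lam)
    ref <- glmnet::glmnet(x, y, lambda = lam, standardize = TRUE,
                          thresh = 1e-12)
    expect_lt(max(abs(ours$coefficients - as.numeric(ref$beta))), 1e-6)
    expect_lt(abs(ours$intercept - as.numeric(ref$a0)), 1e-6)
  }
})

test_that("LOOCV penalty selection favors sparse fits on null data and
           matches an independent cross-validated selector", {
  skip_if_not_installed("glmnet")
  ours <- numeric(40); ref <- numeric(40); ratio <- numeric(40)
  for (s in seq_len(40)) {
    x <- rand_design(50, 5, 1000 + s)
    set.seed(2000 + s); y <- rnorm(50)
    sel <- select_lambda_loocv(x, y)
    ours[s] <- max(abs(fit_lasso(x, y, sel$lambda)$coefficients))
    ratio[s] <- sel$lambda / sel$lambda_grid[1]
    cv <- glmnet::cv.glmnet(x, y, nfolds = 50, grouped = FALSE,
                            lambda = sel$lambda_grid)
    ref[s] <- max(abs(as.numeric(
      glmnet::glmnet(x, y, lambda = cv$lambda.min)$beta)))
  }
  # seed-by-seed agreement with the independent selector
  expect_true(all(abs(ours - ref) < 0.02))
  # near-null selections occur exactly as often as under the oracle, and
  # the chosen penalty is typically a large fraction of lambda_max
  expect_equal(mean(ours < 0.05), mean(ref < 0.05))
  expect_gte(mean(ratio >= 0.5), 0.6)
})

test_that("LOOCV penalty selection beats the variance on strong signal", {
  x <- rand_design(100, 5, 7)
  y <- signal_outcome(x, 0.9, 7)
  sel <- select_lambda_loocv(x, y)
  expect_lt(min(sel$cv_mse), var(y))
  # length-1 grid returns that penalty; ties break to the larger penalty
  expect_equal(select_lambda_loocv(x, y, lambda_grid = 0.123)$lambda, 0.123)
  expect_error(select_lambda_loocv(x[1:2, ], y[1:2]), "at least 3")
})

test_that("corrected R2 is exact for deterministic relationships", {
  x <- rand_design(40, 1, 8)
  y <- 3 * x[, 1] - 1
  r2 <- loocv_corrected_r2(x, y, method = "ols")
  expect_equal(r2$r2_corrected, 1, tolerance = 1e-8)
  expect_equal(r2$r2_apparent, 1, tolerance = 1e-8)
  # the lasso grid floors at 0.001 * lambda_max, so a noiseless fit keeps a
  # penalty-bias residual of that order
  r <- loocv_corrected_r2(x, y, method = "lasso")
  expect_equal(r$r2_corrected, 1, tolerance = 1e-5)
  expect_equal(r$r2_apparent, 1, tolerance = 1e-5)
})

test_that("optimism is positive in expectation on null data", {
  # OLS route (exact hat-matrix LOOCV keeps this cheap over many seeds)
  res <- t(sapply(1:50, function(s) {
    x <- rand_design(60, 8, 3000 + s)
    set.seed(4000 + s); y <- rnorm(60)
    r <- loocv_corrected_r2(x, y, method = "ols")
    c(r$r2_apparent, r$r2_corrected)
  }))
  expect_gt(mean(res[, 1]), mean(res[, 2]))
  expect_gt(mean(res[, 1] - res[, 2]), 0.05)
  # lasso route, fewer seeds
  resl <- t(sapply(1:8, function(s) {
    x <- rand_design(60, 8, 5000 + s)
    set.seed(6000 + s); y <- rnorm(60)
    r <- loocv_corrected_r2(x, y, method = "lasso")
    c(r$r2_apparent, r$r2_corrected)
  }))
  expect_gt(mean(resl[, 1]), mean(resl[, 2]))
})

test_that("missing outcomes are dropped and inputs validated", {
  x <- rand_design(30, 3, 9)
  y <- signal_outcome(x, 0.5, 9)
  y[c(3, 7)] <- NA
  r <- loocv_corrected_r2(x, y, method = "ols")
  expect_equal(r$n_used, 28)
  expect_error(loocv_corrected_r2(x[1:4, ], y[1:4]), "at least 5")
  expect_error(loocv_corrected_r2(x, rep(2, 30)), "zero-variance")
})
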