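#' Ordinary least squares fit
#'
#' Least-squares solution with an explicit intercept. Rank-deficient designs
#' fall back to the minimum-norm solution (via the pseudoinverse) and are
#' flagged.
#'
#' @param x predictor matrix (no intercept column).
#' @param y outcome vector, no missing values.
#' @return object of class `linear_fit` with `intercept`, `coefficients`
#'   (aligned to `colnames(x)`), `lambda = 0`, `method = "ols"`,
#'   `rank_deficient` flag.
#' @export
fit_ols <- function(x, y) {
  x <- as.matrix(x)
  if (anyNA(x) || anyNA(y)) stop("missing values in x or y; drop them first")
  n <- nrow(x)
  if (n <= 1) stop("need at least 2 observations")
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  X1 <- cbind(`(Intercept)` = 1, x)
  qr_ <- qr(X1)
  rank_deficient <- qr_$rank < ncol(X1)
  if (!rank_deficient) {
    beta <- qr.coef(qr_, y)
  } else {
    beta <- drop(MASS::ginv(X1) %*% y)   # minimum-norm solution
    names(beta) <- colnames(X1)
    warning("rank-deficient design; returning minimum-norm solution")
  }
  if (var(y) == 0) warning("constant outcome; R-squared undefined downstream")
  new_linear_fit(intercept = beta[1], coefficients = beta[-1],
                 lambda = 0, method = "ols", rank_deficient = rank_deficient)
}

new_linear_fit <- function(intercept, coefficients, lambda, method,
                           rank_deficient = FALSE, lambda_max = NA_real_,
                           objective_trace = NULL) {
  structure(list(intercept = unname(intercept), coefficients = coefficients,
                 lambda = lambda, method = method,
                 rank_deficient = rank_deficient, lambda_max = lambda_max,
                 objective_trace = objective_trace),
            class = "linear_fit")
}

#' @export
predict.linear_fit <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(colnames(x)) && !is.null(names(object$coefficients)) &&
      all(names(object$coefficients) %in% colnames(x)))
    x <- x[, names(object$coefficients), drop = FALSE]
  drop(object$intercept + x %*% object$coefficients)
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("%s fit (lambda = %g), %d predictors, %d nonzero\n",
              x$method, x$lambda, length(x$coefficients),
              sum(x$coefficients != 0)))
  invisible(x)
}

#' Lasso regression by coordinate descent
#'
#' Minimizes `(1/2n) * RSS + lambda * sum(|beta_j|)` with an unpenalized
#' intercept; predictors are standardized internally (population SD) and
#' coefficients are reported on the original scale. At `lambda = 0` the
#' solution coincides with OLS on well-conditioned designs; at
#' `lambda >= max_j |(1/n) x_j'(y - ybar)|` (standardized `x_j`) all slopes
#' are exactly zero.
#'
#' @param x predictor matrix (no intercept column).
#' @param y outcome vector, no missing values.
#' @param lambda non-negative penalty.
#' @param tol convergence tolerance on coefficient changes (default 1e-7).
#' @param maxit sweep cap; reaching it for this convex objective indicates a
#'   bug and errors.
#' @param trace_objective record the penalized objective after every sweep.
#' @return a `linear_fit` (with `lambda_max` and optional `objective_trace`).
#' @export
#' @examples
#' x <- matrix(rnorm(100), 50, 2); y <- x[, 1] + rnorm(50)
#' fit_lasso(x, y, lambda = 0.1)
fit_lasso <- function(x, y, lambda, tol = 1e-7, maxit = 100000,
                      trace_objective = FALSE) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  if (anyNA(x) || anyNA(y)) stop("missing values in x or y; drop them first")
  if (nrow(x) < 2) stop("need at least 2 observations")
  stopifnot_scalar_number(lambda, "lambda", lower = 0)
  res <- cpp_lasso_path(x, as.numeric(y), lambda, tol = tol, maxit = maxit,
                        trace_objective = trace_objective)
  if (max(res$sweeps) >= maxit)
    stop("coordinate descent hit the iteration cap; this should not happen ",
         "for a convex objective -- please report")
  co <- drop(res$coef)
  names(co) <- colnames(x)
  new_linear_fit(intercept = res$intercept[1], coefficients = co,
                 lambda = lambda, method = "lasso",
                 lambda_max = res$lambda_max,
                 objective_trace = if (trace_objective) res$objective_trace)
}

#' Default penalty grid
#'
#' 100 log-spaced values from `lambda_max` (the smallest penalty zeroing all
#' slopes) down to `0.001 * lambda_max`.
#'
#' @param x,y data (used only for `lambda_max`).
#' @param nlambda grid length.
#' @param min_ratio ratio of smallest to largest penalty.
#' @return decreasing numeric vector.
#' @export
lasso_lambda_grid <- function(x, y, nlambda = 100, min_ratio = 1e-3) {
  x <- as.matrix(x)
  n <- nrow(x)
  m <- colMeans(x)
  sdp <- sqrt(colMeans(x^2) - m^2)       # population SD, as in the solver
  b <- (colMeans(x * y) - m * mean(y))
  b <- ifelse(sdp > 1e-10, abs(b) / sdp, 0)
  lmax <- max(b, 1e-300)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

#' Select the lasso penalty by leave-one-out cross-validation
#'
#' Returns the grid value minimizing the LOOCV mean squared error
#' `sum_i (y_i - yhat_{-i}(lambda))^2 / n`, the model being refit from
#' scratch on each fold. Ties are broken toward the larger penalty (the
#' sparser model).
#'
#' @param x,y data, no missing values.
#' @param lambda_grid candidate penalties (default [lasso_lambda_grid()]).
#' @param tol,maxit passed to the solver.
#' @return list with `lambda` (the selected value), `cv_mse` (per grid
#'   point) and `lambda_grid`.
#' @export
select_lambda_loocv <- function(x, y, lambda_grid = NULL,
                                tol = 1e-7, maxit = 100000) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  if (nrow(x) < 3) stop("need at least 3 observations for LOOCV")
  if (is.null(lambda_grid)) lambda_grid <- lasso_lambda_grid(x, y)
  if (!length(lambda_grid)) stop("empty lambda grid")
  ord <- order(lambda_grid, decreasing = TRUE)
  grid <- lambda_grid[ord]
  mse <- cpp_loocv_mse(x, as.numeric(y), grid, tol = tol, maxit = maxit)
  best <- 1L
  for (s in seq_along(grid))
    if (mse[s] < mse[best] - 1e-12) best <- s
  list(lambda = grid[best], cv_mse = mse, lambda_grid = grid)
}

#' Optimism-corrected R-squared by leave-one-out cross-validation
#'
#' For every row the entire modeling procedure -- including, for the lasso,
#' re-selection of the penalty by an inner LOOCV on the remaining rows -- is
#' refit without that row, and the held-out prediction is scored. The
#' corrected R-squared is `1 - sum(y_i - yhat_{-i})^2 / sum(y_i - ybar)^2`
#' with `ybar` the full-sample mean; values can be negative when the model
#' predicts worse than the mean. The apparent R-squared comes from the
#' full-data fit.
#'
#' @param x predictor matrix, complete (impute first).
#' @param y outcome; rows with missing `y` are dropped (with their `x`).
#' @param method `"lasso"` (default) or `"ols"`.
#' @param nested for the lasso, re-select the penalty inside every outer
#'   fold (default TRUE). With `FALSE`, the penalty is selected once on the
#'   full data and held fixed while each fold is refit.
#' @param nlambda,min_ratio penalty-grid geometry.
#' @param outcome,timepoint_label optional labels carried into the record.
#' @return object of class `cv_performance`: `outcome`, `timepoint_label`,
#'   `n_used`, `r2_apparent`, `r2_corrected`, `method`, `lambda` (full-data
#'   selected penalty, lasso only).
#' @export
loocv_corrected_r2 <- function(x, y, method = c("lasso", "ols"),
                               nested = TRUE, nlambda = 100,
                               min_ratio = 1e-3,
                               outcome = NA_character_,
                               timepoint_label = NA_character_) {
  method <- match.arg(method)
  x <- as.matrix(x); storage.mode(x) <- "double"
  keep <- !is.na(y)
  x <- x[keep, , drop = FALSE]; y <- as.numeric(y[keep])
  n <- length(y)
  if (n < 5) stop("need at least 5 observations with the outcome observed")
  if (var(y) == 0) stop("zero-variance outcome")

  if (method == "ols") {
    fit <- fit_ols(x, y)
    X1 <- cbind(1, x)
    # exact LOOCV for least squares via the hat matrix
    qr_ <- qr(X1)
    h <- rowSums(qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]^2)
    resid <- y - predict(fit, x)
    pred_loo <- y - resid / pmax(1 - h, 1e-12)
    lambda_full <- NA_real_
    r2_app <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  } else {
    sel <- select_lambda_loocv(x, y, lasso_lambda_grid(x, y, nlambda,
                                                       min_ratio))
    lambda_full <- sel$lambda
    fit <- fit_lasso(x, y, lambda_full)
    r2_app <- 1 - sum((y - predict(fit, x))^2) / sum((y - mean(y))^2)
    cv <- cpp_nested_loocv(x, y, nlambda = nlambda, min_ratio = min_ratio,
                           nested = nested, lambda_fixed = lambda_full)
    pred_loo <- cv$pred
  }
  r2_corr <- 1 - sum((y - pred_loo)^2) / sum((y - mean(y))^2)
  structure(list(outcome = outcome, timepoint_label = timepoint_label,
                 n_used = n, r2_apparent = r2_app, r2_corrected = r2_corr,
                 method = method, lambda = lambda_full, fit = fit),
            class = "cv_performance")
}

#' @export
print.cv_performance <- function(x, ...) {
  cat(sprintf("%s | %s | n = %d | R2 apparent = %.3f, corrected = %.3f (%s)\n",
              x$outcome, x$timepoint_label, x$n_used, x$r2_apparent,
              x$r2_corrected, x$method))
  invisible(x)
}

#' @export
as.data.frame.cv_performance <- function(x, ...) {
  data.frame(outcome = x$outcome, timepoint = x$timepoint_label,
             n = x$n_used, r2_apparent = x$r2_apparent,
             r2_corrected = x$r2_corrected, method = x$method,
             stringsAsFactors = FALSE)
}
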