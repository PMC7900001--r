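#' Jointly model all outcomes with correlated residuals
#'
#' Two-stage estimator of the joint outcome model used for composite
#' prediction intervals. With an identical predictor set across outcomes,
#' per-outcome coefficients are the outcome-wise least-squares fits
#' (continuous outcomes, on the standardized/oriented scale) and cumulative
#' probit MLEs (ordinal outcomes, on the unit-residual-variance latent
#' scale); the residual correlation matrix is assembled from pairwise
#' Pearson (continuous-continuous), conditional polyserial
#' (continuous-ordinal) and conditional polychoric (ordinal-ordinal)
#' estimates, then projected to the nearest positive-semidefinite
#' correlation matrix if needed (the Frobenius adjustment distance is
#' recorded). This coincides with the weighted-least-squares structural
#' equation solution when all outcomes share one regressor set.
#'
#' Outcomes must be complete: impute them first (the same k-nearest-neighbor
#' imputation as predictors) via [knn_impute()].
#'
#' @param table cohort table with complete predictors and outcomes.
#' @param spec a [predictor_set_spec()] giving the shared predictor set.
#' @param outcome_meta data.frame with columns `name`, `kind`
#'   (`"continuous"`/`"ordinal"`), `orientation`; defaults to the synthetic
#'   cohort's own outcome specs.
#' @return object of class `joint_outcome_model`: coefficient matrix `B`
#'   (K x (p+1), intercept first), residual correlation `R`, residual SDs
#'   `sigma` (1 on the latent scale for ordinal outcomes), ordinal
#'   `thresholds`, design Gram inverse `G`, outcome `transform`
#'   (means/SDs/signs), `psd_adjustment`, `n`.
#' @export
fit_joint_model <- function(table, spec, outcome_meta = NULL) {
  stopifnot(inherits(spec, "predictor_set_spec"))
  if (is.null(outcome_meta)) {
    gt <- ground_truth(table)
    if (is.null(gt)) stop("supply `outcome_meta` for non-synthetic tables")
    specs <- gt$config$outcome_specs
    outcome_meta <- data.frame(
      name = vapply(specs, `[[`, "", "name"),
      kind = vapply(specs, `[[`, "", "kind"),
      orientation = vapply(specs, `[[`, "", "orientation"),
      stringsAsFactors = FALSE)
  }
  K <- nrow(outcome_meta)
  am <- assemble_predictors(table, spec)
  if (anyNA(am$x)) stop("predictors contain missing values; impute first")
  ymat <- as.data.frame(table)[, outcome_meta$name, drop = FALSE]
  if (anyNA(ymat)) stop("outcomes contain missing values; impute them first")
  n <- nrow(am$x)
  X1 <- cbind(`(Intercept)` = 1, am$x)
  p1 <- ncol(X1)
  if (n <= p1) stop("fewer rows than predictors; cannot fit the joint model")
  G <- solve(crossprod(X1))

  cont <- which(outcome_meta$kind == "continuous")
  ords <- which(outcome_meta$kind == "ordinal")

  or_map <- stats::setNames(
    ifelse(outcome_meta$orientation == "higher_more_severe", -1, 1),
    outcome_meta$name)
  std <- standardize_outcomes(table, outcome_meta$name[cont],
                              orientation_map = or_map)
  B <- matrix(0, K, p1, dimnames = list(outcome_meta$name, colnames(X1)))
  sigma <- stats::setNames(rep(1, K), outcome_meta$name)
  resid_std <- matrix(NA_real_, n, K,
                      dimnames = list(NULL, outcome_meta$name))
  thresholds <- stats::setNames(vector("list", K), outcome_meta$name)
  ord_bounds <- stats::setNames(vector("list", K), outcome_meta$name)
  fits <- stats::setNames(vector("list", K), outcome_meta$name)

  for (i in cont) {
    nm <- outcome_meta$name[i]
    yz <- std$table[[nm]]
    co <- qr.coef(qr(X1), yz)
    B[i, ] <- co
    e <- yz - drop(X1 %*% co)
    sigma[nm] <- sqrt(sum(e^2) / (n - p1))
    resid_std[, i] <- e / sigma[nm]
  }
  for (i in ords) {
    nm <- outcome_meta$name[i]
    y <- ymat[[nm]]
    if (or_map[[nm]] < 0) y <- max(y) + min(y) - y   # reverse-score levels
    fit <- fit_propodds(am$x, y, link = "probit")
    fits[[nm]] <- fit
    eta <- predict(fit, am$x, type = "lp")
    # center the latent prediction at the training mean so ordinal
    # components sit on a mean-zero scale comparable to the standardized
    # continuous outcomes
    B[i, 1] <- -mean(eta)
    B[i, match(names(fit$coefficients), colnames(X1))] <- fit$coefficients
    thresholds[[nm]] <- fit$thresholds - mean(eta)
    ji <- match(y, fit$level_values)
    ord_bounds[[nm]] <- list(
      lo = c(-Inf, fit$thresholds)[ji] - eta,
      up = c(fit$thresholds, Inf)[ji] - eta)
  }

  R <- diag(K)
  dimnames(R) <- list(outcome_meta$name, outcome_meta$name)
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    ka <- outcome_meta$kind[a]; kb <- outcome_meta$kind[b]
    r <- if (ka == "continuous" && kb == "continuous") {
      cor(resid_std[, a], resid_std[, b])
    } else if (ka == "continuous") {
      bb <- ord_bounds[[b]]
      polyserial_residual(resid_std[, a], bb$lo, bb$up)
    } else if (kb == "continuous") {
      aa <- ord_bounds[[a]]
      polyserial_residual(resid_std[, b], aa$lo, aa$up)
    } else {
      aa <- ord_bounds[[a]]; bb <- ord_bounds[[b]]
      polychoric_residual(aa$lo, aa$up, bb$lo, bb$up)
    }
    R[a, b] <- R[b, a] <- r
  }
  psd_adjustment <- 0
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    Rp <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    dimnames(Rp) <- dimnames(R)
    psd_adjustment <- norm(R - Rp, "F")
    R <- Rp
  }

  structure(list(B = B, R = R, sigma = sigma, thresholds = thresholds,
                 G = G, transform = std$transform,
                 outcome_meta = outcome_meta, ordinal_fits = fits,
                 predictor_columns = spec$columns,
                 timepoint_label = spec$timepoint_label,
                 psd_adjustment = psd_adjustment, n = n),
            class = "joint_outcome_model")
}

#' @export
print.joint_outcome_model <- function(x, ...) {
  cat(sprintf(
    "joint outcome model: %d outcomes (%d continuous, %d ordinal), %d predictors, n = %d\n",
    nrow(x$B), sum(x$outcome_meta$kind == "continuous"),
    sum(x$outcome_meta$kind == "ordinal"), ncol(x$B) - 1, x$n))
  if (x$psd_adjustment > 0)
    cat(sprintf("residual correlation projected to nearest PSD (Frobenius %.3g)\n",
                x$psd_adjustment))
  invisible(x)
}

joint_design_row <- function(model, x_new) {
  cols <- model$predictor_columns
  if (is.list(x_new)) x_new <- unlist(x_new)
  if (!is.null(names(x_new))) {
    absent <- setdiff(cols, names(x_new))
    if (length(absent))
      stop("x_new lacks predictor(s): ", paste(absent, collapse = ", "))
    x_new <- x_new[cols]
  } else if (length(x_new) != length(cols)) {
    stop("x_new must have one value per predictor column")
  }
  if (anyNA(x_new)) stop("x_new must be complete")
  c(1, as.numeric(x_new))
}

new_composite_prediction <- function(point, se, level, weights, outcome,
                                     thresholds = NULL, leverage = NA_real_) {
  z <- qnorm((1 + level) / 2)
  structure(list(point = point, se_pred = se,
                 interval = c(lo = point - z * se, hi = point + z * se),
                 level = level, weights = weights, outcome = outcome,
                 thresholds = thresholds, leverage = leverage),
            class = "composite_prediction")
}

#' @export
print.composite_prediction <- function(x, ...) {
  cat(sprintf("%s: %.3f [%.3f, %.3f] (%.0f%% prediction interval)\n",
              x$outcome %||% "composite", x$point, x$interval[1],
              x$interval[2], 100 * x$level))
  invisible(x)
}

#' Prediction interval for a single outcome
#'
#' On the standardized (continuous) or unit-residual-variance latent probit
#' (ordinal) scale: point `x'B_k` and
#' `se_pred^2 = sigma_kk^2 * (1 + x'Gx)`, combining residual variance with
#' parameter-estimation uncertainty through the training design Gram
#' inverse. Ordinal intervals are reported on the latent scale with the
#' (centered) threshold positions attached for interpretation.
#'
#' @param model a [fit_joint_model()] result.
#' @param x_new named vector of predictor values (no intercept).
#' @param outcome outcome name.
#' @param level interval coverage (default 0.95).
#' @return a `composite_prediction`.
#' @export
predict_outcome_interval <- function(model, x_new, outcome, level = 0.95) {
  stopifnot(inherits(model, "joint_outcome_model"))
  k <- match(outcome, rownames(model$B))
  if (is.na(k)) stop("unknown outcome: ", outcome)
  x1 <- joint_design_row(model, x_new)
  lev_g <- drop(t(x1) %*% model$G %*% x1)
  point <- drop(model$B[k, ] %*% x1)
  se <- model$sigma[[k]] * sqrt(1 + lev_g)
  new_composite_prediction(point, se, level,
                           weights = NULL, outcome = outcome,
                           thresholds = model$thresholds[[outcome]],
                           leverage = lev_g)
}

#' Prediction interval for a priority-weighted composite outcome
#'
#' Point prediction `w'(B x)` and
#' `se_pred^2 = (1 + x'Gx) * (w' Rtilde w)` with `Rtilde = D R D` the
#' residual covariance on the standardized scale (`D` the residual SDs,
#' unit for ordinal latents). With a one-hot weight vector this reduces
#' exactly to [predict_outcome_interval()]; weakly correlated residuals
#' make composites of many outcomes tighter than any single component.
#'
#' @param model a [fit_joint_model()] result.
#' @param x_new named predictor vector.
#' @param w non-negative weight vector of length K (e.g. from
#'   [map_priorities_to_weights()]).
#' @param level interval coverage (default 0.95).
#' @return a `composite_prediction`.
#' @export
predict_composite_interval <- function(model, x_new, w, level = 0.95) {
  stopifnot(inherits(model, "joint_outcome_model"))
  K <- nrow(model$B)
  if (!is.null(names(w))) {
    absent <- setdiff(rownames(model$B), names(w))
    if (length(absent) == 0) w <- w[rownames(model$B)]
  }
  if (length(w) != K) stop("w must have one weight per outcome")
  if (any(w < 0)) stop("weights must be non-negative")
  if (all(w == 0)) stop("all-zero weight vector")
  x1 <- joint_design_row(model, x_new)
  lev_g <- drop(t(x1) %*% model$G %*% x1)
  point <- drop(t(w) %*% (model$B %*% x1))
  Rt <- diag(model$sigma) %*% model$R %*% diag(model$sigma)
  se <- sqrt((1 + lev_g) * drop(t(w) %*% Rt %*% w))
  new_composite_prediction(point, se, level, weights = w,
                           outcome = NULL, leverage = lev_g)
}
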