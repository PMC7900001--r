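#' Proportional-odds (cumulative link) regression
#'
#' Maximum-likelihood fit of the cumulative model
#' `P(Y <= j | x) = F(theta_j - x'beta)` with a logistic (proportional
#' odds) or standard-normal (probit, used for the joint latent outcome
#' model) link. Thresholds are kept strictly increasing by optimizing
#' `(theta_1, log(theta_2 - theta_1), ...)` unconstrained; convergence
#' requires a gradient max-norm below `grad_tol`. Levels absent from `y`
#' are collapsed away (the observed level set is recorded).
#'
#' @param x predictor matrix (no intercept; may have zero columns for an
#'   intercept-only model). Rows with missing `y` are dropped.
#' @param y ordinal outcome (numeric levels).
#' @param link `"logit"` or `"probit"`.
#' @param grad_tol gradient max-norm at the optimum (default 1e-6).
#' @return object of class `ordinal_fit`: `thresholds`, `coefficients`,
#'   `n_levels`, `level_values`, `vcov`, `logLik`, `converged`,
#'   `separation_suspected`, `link`, `n`.
#' @export
#' @examples
#' y <- rep(c(1, 2, 3), c(25, 50, 25))
#' fit_propodds(matrix(nrow = 100, ncol = 0), y)$thresholds  # +/- logit(.25)
fit_propodds <- function(x, y, link = c("logit", "probit"),
                         grad_tol = 1e-6) {
  link <- match.arg(link)
  x <- as.matrix(x); storage.mode(x) <- "double"
  keep <- !is.na(y)
  x <- x[keep, , drop = FALSE]; y <- y[keep]
  if (anyNA(x)) stop("missing predictor values; impute first")
  lev <- sort(unique(y))
  J <- length(lev)
  if (J < 2) stop("need at least 2 observed outcome levels")
  yi <- match(y, lev)
  n <- length(yi); p <- ncol(x)

  F_ <- if (link == "logit") plogis else pnorm
  f_ <- if (link == "logit") dlogis else dnorm
  linkfun <- if (link == "logit") qlogis else qnorm

  theta_of <- function(par) {
    z <- par[seq_len(J - 1)]
    if (J == 2) z[1] else cumsum(c(z[1], exp(z[-1])))
  }

  nll_parts <- function(theta, beta) {
    eta <- if (p) drop(x %*% beta) else numeric(n)
    up <- c(theta, Inf)[yi] - eta
    lo <- c(-Inf, theta)[yi] - eta
    P <- pmax(F_(up) - F_(lo), 1e-300)
    list(eta = eta, up = up, lo = lo, P = P)
  }

  nll <- function(par) {
    pr <- nll_parts(theta_of(par), par[J - 1 + seq_len(p)])
    -sum(log(pr$P))
  }

  grad_natural <- function(theta, beta) {
    pr <- nll_parts(theta, beta)
    fu <- ifelse(is.finite(pr$up), f_(pr$up), 0)
    fl <- ifelse(is.finite(pr$lo), f_(pr$lo), 0)
    gtheta <- numeric(J - 1)
    wU <- -fu / pr$P    # d(-logP)/d theta_{j}   for obs at level j (j < J)
    wL <- fl / pr$P     # d(-logP)/d theta_{j-1} for obs at level j (j > 1)
    for (m in seq_len(J - 1)) {
      gtheta[m] <- sum(wU[yi == m]) + sum(wL[yi == m + 1])
    }
    gbeta <- if (p) drop(crossprod(x, (fu - fl) / pr$P)) else numeric(0)
    c(gtheta, gbeta)
  }

  grad <- function(par) {
    theta <- theta_of(par)
    g <- grad_natural(theta, par[J - 1 + seq_len(p)])
    gt <- g[seq_len(J - 1)]
    gz <- numeric(J - 1)
    gz[1] <- sum(gt)
    if (J > 2) for (m in 2:(J - 1))
      gz[m] <- exp(par[m]) * sum(gt[m:(J - 1)])
    c(gz, g[J - 1 + seq_len(p)])
  }

  cum <- cumsum(tabulate(yi, J))[seq_len(J - 1)] / n
  theta0 <- linkfun(cum)
  par0 <- c(theta0[1], if (J > 2) log(pmax(diff(theta0), 1e-3)), rep(0, p))

  opt <- optim(par0, nll, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  theta <- theta_of(opt$par)
  beta <- opt$par[J - 1 + seq_len(p)]

  nll_natural <- function(theta, beta) -sum(log(nll_parts(theta, beta)$P))
  # Newton polish in the natural parameterization: BFGS typically stops
  # with the gradient near, but not under, the requested tolerance
  cur <- nll_natural(theta, beta)
  for (it in seq_len(50)) {
    g <- grad_natural(theta, beta)
    if (max(abs(g)) < grad_tol) break
    H <- optimHess(c(theta, beta),
                   fn = function(q) nll_natural(q[seq_len(J - 1)],
                                                q[J - 1 + seq_len(p)]),
                   gr = function(q) grad_natural(q[seq_len(J - 1)],
                                                 q[J - 1 + seq_len(p)]))
    step <- tryCatch(solve(H, g), error = function(e) g * 1e-4)
    s <- 1; moved <- FALSE
    while (s > 1e-10) {
      qn <- c(theta, beta) - s * step
      thn <- qn[seq_len(J - 1)]
      if (J == 2 || all(diff(thn) > 0)) {
        val <- nll_natural(thn, qn[J - 1 + seq_len(p)])
        if (is.finite(val) && val <= cur + 1e-12) {
          theta <- thn; beta <- qn[J - 1 + seq_len(p)]
          cur <- val; moved <- TRUE; break
        }
      }
      s <- s / 2
    }
    if (!moved) break
  }
  names(beta) <- colnames(x)
  gnorm <- max(abs(grad_natural(theta, beta)))
  converged <- gnorm < grad_tol
  separation <- !converged && (any(abs(beta) > 25) || any(abs(theta) > 50))
  if (separation)
    warning("possible complete separation: fit did not converge and ",
            "coefficients are extreme")

  vc <- tryCatch({
    H <- optimHess(c(theta, beta),
                   fn = function(q) {
                     th <- q[seq_len(J - 1)]
                     if (any(diff(th) <= 0)) return(1e10)
                     -sum(log(nll_parts(th, q[J - 1 + seq_len(p)])$P))
                   },
                   gr = function(q) grad_natural(q[seq_len(J - 1)],
                                                 q[J - 1 + seq_len(p)]))
    solve(H)
  }, error = function(e) matrix(NA_real_, J - 1 + p, J - 1 + p))
  nm <- c(paste0("theta_", seq_len(J - 1)),
          colnames(x) %||% (if (p) paste0("x", seq_len(p)) else NULL))
  dimnames(vc) <- list(nm, nm)

  structure(list(thresholds = theta, coefficients = beta, n_levels = J,
                 level_values = lev, vcov = vc, logLik = -opt$value,
                 converged = converged, grad_norm = gnorm,
                 separation_suspected = separation, link = link, n = n),
            class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat(sprintf("cumulative %s model: %d levels, %d predictors, n = %d%s\n",
              x$link, x$n_levels, length(x$coefficients), x$n,
              if (x$converged) "" else " (NOT converged)"))
  cat("thresholds:", signif(x$thresholds, 4), "\n")
  if (length(x$coefficients)) print(signif(x$coefficients, 4))
  invisible(x)
}

#' Predictions from a cumulative-link fit
#'
#' @param object an `ordinal_fit`.
#' @param newdata predictor matrix.
#' @param type `"lp"` (linear predictor `x'beta`, the concordance score),
#'   `"cumprob"` (matrix of `P(Y <= j | x)`) or `"prob"` (category
#'   probabilities).
#' @param ... unused.
#' @export
predict.ordinal_fit <- function(object, newdata,
                                type = c("lp", "cumprob", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (!is.null(colnames(x)) && length(object$coefficients) &&
      all(names(object$coefficients) %in% colnames(x)))
    x <- x[, names(object$coefficients), drop = FALSE]
  eta <- if (length(object$coefficients)) drop(x %*% object$coefficients)
  else numeric(nrow(x))
  if (type == "lp") return(eta)
  F_ <- if (object$link == "logit") plogis else pnorm
  cm <- vapply(object$thresholds, function(th) F_(th - eta),
               numeric(length(eta)))
  cm <- matrix(cm, nrow = length(eta))
  cm <- cbind(cm, 1)
  colnames(cm) <- paste0("le_", object$level_values)
  if (type == "cumprob") return(cm)
  pr <- cbind(cm[, 1, drop = FALSE], t(diff(t(cm))))
  colnames(pr) <- paste0("p_", object$level_values)
  pr
}

#' Generalized c-statistic for ordinal outcomes
#'
#' Over all pairs with different outcome levels, the proportion in which the
#' member with the higher outcome has the higher score, counting score ties
#' one-half. Computed per level pair via rank sums (Mann-Whitney), which
#' matches brute-force pair enumeration exactly.
#'
#' @param scores numeric risk scores (higher = higher predicted level).
#' @param y ordinal outcome.
#' @return a number in `[0, 1]`.
#' @export
#' @examples
#' c_statistic(c(0.1, 0.5, 0.5, 0.9), c(1, 1, 2, 3))  # 0.9
c_statistic <- function(scores, y) {
  if (length(scores) != length(y)) stop("length mismatch")
  keep <- !is.na(scores) & !is.na(y)
  scores <- scores[keep]; y <- y[keep]
  lev <- sort(unique(y))
  if (length(lev) < 2) stop("all outcome values identical: c undefined")
  conc <- 0; tot <- 0
  for (a in seq_len(length(lev) - 1)) for (b in (a + 1):length(lev)) {
    slo <- scores[y == lev[a]]; shi <- scores[y == lev[b]]
    nlo <- length(slo); nhi <- length(shi)
    r <- rank(c(slo, shi))                       # midranks handle ties
    U <- sum(r[nlo + seq_len(nhi)]) - nhi * (nhi + 1) / 2
    conc <- conc + U                             # wins + 0.5 * score ties
    tot <- tot + nlo * nhi
  }
  conc / tot
}

#' Bootstrap optimism-corrected c-statistic
#'
#' Harrell's optimism bootstrap: for each of `n_boot` seeded resamples
#' (with replacement, size n) the model is refit and its optimism is the
#' difference between its c on the resample and its c on the original data;
#' the corrected c is the apparent c minus the mean optimism. Resamples
#' missing an observed outcome level are redrawn (up to 100 times, then
#' that repetition is skipped and logged).
#'
#' @param x predictor matrix (complete).
#' @param y ordinal outcome; rows with missing `y` are dropped.
#' @param n_boot bootstrap repetitions (default 40).
#' @param seed integer seed.
#' @param link passed to [fit_propodds()].
#' @param outcome,timepoint_label optional labels.
#' @return object of class `cstat_result`: `c_apparent`, `optimism`,
#'   `c_corrected`, `n_boot_used`, `n_skipped`, `seed`, `n_used`.
#' @export
bootstrap_corrected_c <- function(x, y, n_boot = 40, seed = 1,
                                  link = "logit",
                                  outcome = NA_character_,
                                  timepoint_label = NA_character_) {
  x <- as.matrix(x)
  keep <- !is.na(y)
  x <- x[keep, , drop = FALSE]; y <- y[keep]
  n <- length(y)
  full <- fit_propodds(x, y, link = link)
  c_app <- c_statistic(predict(full, x, type = "lp"), y)
  lev <- sort(unique(y))

  opt <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- NULL
      for (try in seq_len(100)) {
        cand <- sample.int(n, n, replace = TRUE)
        if (all(lev %in% y[cand])) { idx <- cand; break }
      }
      if (is.null(idx)) return(NA_real_)
      fb <- suppressWarnings(fit_propodds(x[idx, , drop = FALSE], y[idx],
                                          link = link))
      c_boot <- c_statistic(predict(fb, x[idx, , drop = FALSE], "lp"),
                            y[idx])
      c_orig <- c_statistic(predict(fb, x, "lp"), y)
      c_boot - c_orig
    }, 0)
  })
  skipped <- sum(is.na(opt))
  if (skipped > 0)
    message(skipped, " bootstrap repetition(s) skipped: could not draw a ",
            "resample containing every outcome level")
  used <- n_boot - skipped
  if (used < 10)
    stop("fewer than 10 usable bootstrap repetitions")
  optimism <- mean(opt, na.rm = TRUE)
  structure(list(outcome = outcome, timepoint_label = timepoint_label,
                 c_apparent = c_app, optimism = optimism,
                 c_corrected = c_app - optimism, n_boot = n_boot,
                 n_boot_used = used, n_skipped = skipped, seed = seed,
                 n_used = n),
            class = "cstat_result")
}

#' @export
print.cstat_result <- function(x, ...) {
  cat(sprintf(
    "%s | %s | n = %d | c apparent = %.3f, corrected = %.3f (%d boot)\n",
    x$outcome, x$timepoint_label, x$n_used, x$c_apparent, x$c_corrected,
    x$n_boot_used))
  invisible(x)
}

#' @export
as.data.frame.cstat_result <- function(x, ...) {
  data.frame(outcome = x$outcome, timepoint = x$timepoint_label,
             n = x$n_used, c_apparent = x$c_apparent,
             c_corrected = x$c_corrected, n_boot = x$n_boot_used,
             seed = x$seed, stringsAsFactors = FALSE)
}
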