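#' Specify a generative adult outcome
#'
#' Describes one adult outcome of the synthetic cohort: either a continuous
#' measure generated as `intercept + loadings' z + residual_sd * e`, or an
#' ordinal measure obtained by thresholding a unit-residual-variance latent
#' normal `loadings' z + e`. The residuals `e` across outcomes share the
#' cohort-level residual correlation matrix, which is what later powers
#' composite prediction intervals.
#'
#' @param name column name of the outcome.
#' @param kind `"continuous"` or `"ordinal"`.
#' @param loadings named numeric vector of coefficients on the generator's
#'   latent predictor scores (names like `"viq_9"`); may be empty for a
#'   pure-noise outcome.
#' @param residual_sd residual standard deviation (continuous outcomes);
#'   fixed at 1 on the latent scale for ordinal outcomes.
#' @param intercept mean shift placing the outcome on its reporting scale.
#' @param n_levels number of ordinal levels (>= 2; ordinal only).
#' @param thresholds strictly increasing cut points of length `n_levels - 1`
#'   on the latent scale (ordinal only).
#' @param level_values observed values the ordinal levels map to
#'   (default `1:n_levels`; e.g. `0:3` for a 0-3 scale).
#' @param orientation `"higher_less_severe"` or `"higher_more_severe"`; used
#'   later when outcomes are reverse-scored onto a common direction.
#' @param range_clip optional `c(min, max)` plausibility clipping, off by
#'   default because clipping distorts variance-recovery checks.
#' @return an object of class `outcome_spec`.
#' @export
#' @examples
#' outcome_spec("out_viq", loadings = c(viq_9 = 42), residual_sd = 16,
#'              intercept = 62)
outcome_spec <- function(name,
                         kind = c("continuous", "ordinal"),
                         loadings = numeric(),
                         residual_sd = 1,
                         intercept = 0,
                         n_levels = NULL,
                         thresholds = NULL,
                         level_values = NULL,
                         orientation = c("higher_less_severe",
                                         "higher_more_severe"),
                         range_clip = NULL) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  if (length(loadings) && is.null(names(loadings)))
    stop("`loadings` must be a named vector (names = latent predictor scores)")
  if (kind == "continuous") {
    stopifnot_scalar_number(residual_sd, "residual_sd", lower = 1e-12)
  } else {
    residual_sd <- 1
    if (is.null(n_levels) || n_levels < 2 || !is_wholenumber(n_levels))
      stop("ordinal outcomes need integer `n_levels` >= 2")
    if (is.null(thresholds) || length(thresholds) != n_levels - 1)
      stop("`thresholds` must have length n_levels - 1")
    if (any(diff(thresholds) <= 0))
      stop("`thresholds` must be strictly increasing")
    level_values <- level_values %||% seq_len(n_levels)
    if (length(level_values) != n_levels)
      stop("`level_values` must have length n_levels")
  }
  if (!is.null(range_clip) &&
      (length(range_clip) != 2 || range_clip[1] >= range_clip[2]))
    stop("`range_clip` must be c(min, max) with min < max")
  structure(list(name = name, kind = kind, loadings = loadings,
                 residual_sd = residual_sd, intercept = intercept,
                 n_levels = n_levels, thresholds = thresholds,
                 level_values = level_values, orientation = orientation,
                 range_clip = range_clip),
            class = "outcome_spec")
}

#' Ground-truth population R-squared of an outcome specification
#'
#' Returns `b' S b / (b' S b + sigma^2)` for loading vector `b`, predictor
#' covariance `S` and residual standard deviation `sigma` -- the proportion of
#' outcome variance explained by the generative linear predictor. For ordinal
#' outcomes this is on the latent (unit-residual-variance) scale.
#'
#' @param spec an [outcome_spec()].
#' @param predictor_cov covariance matrix of the latent predictor scores the
#'   loadings refer to; its dimnames (if any) must cover the loading names.
#' @return a number in `[0, 1)`.
#' @export
population_r2 <- function(spec, predictor_cov) {
  stopifnot(inherits(spec, "outcome_spec"))
  b <- spec$loadings
  if (!length(b)) return(0)
  if (!is.matrix(predictor_cov) ||
      nrow(predictor_cov) != ncol(predictor_cov))
    stop("`predictor_cov` must be a square matrix")
  if (!is.null(rownames(predictor_cov))) {
    missing_nm <- setdiff(names(b), rownames(predictor_cov))
    if (length(missing_nm))
      stop("predictor_cov lacks loading columns: ",
           paste(missing_nm, collapse = ", "))
    predictor_cov <- predictor_cov[names(b), names(b), drop = FALSE]
  } else if (nrow(predictor_cov) != length(b)) {
    stop("`predictor_cov` not conformable with loadings")
  }
  explained <- drop(t(b) %*% predictor_cov %*% b)
  explained / (explained + spec$residual_sd^2)
}

# One repeated measure of the longitudinal battery: observed score at
# assessment age t is mean_t + sd_t * z_t with z_t = w*g + sqrt(1-w^2)*a_t,
# g a participant-level severity factor and a_t stationary AR(1).
measure_spec <- function(name, ages, means, sds, w, phi) {
  means <- rep_len(means, length(ages)); sds <- rep_len(sds, length(ages))
  stopifnot(abs(w) < 1, phi >= 0, phi <= 1, all(sds > 0))
  list(name = name, ages = ages, means = means, sds = sds, w = w, phi = phi)
}

#' Default longitudinal predictor battery
#'
#' Verbal and non-verbal IQ, autism symptom severity (CSS) and daily-living
#' skills assessed at ages 2, 3, 5 and 9; irritability and hyperactivity at
#' 9, 14 and 17; CBCL total at 9 and 15; teacher-rated SDQ emotion and
#' prosocial subscales at 14 and 17; plus demographics (female,
#' non-Caucasian, maternal education 1-5) and an autism-diagnosis indicator
#' at ages 2-9. Marginal means and SDs are loosely calibrated to a referral
#' cohort of toddlers assessed for possible autism. Each measure carries a
#' loading `w` on a shared severity factor (negative for skills where higher
#' scores mean less severe impact) and an AR(1) autocorrelation `phi` across
#' its own assessments.
#'
#' @return a list with elements `measures`, `p_female`, `p_noncauc`,
#'   `mat_edu_probs`, and autism-diagnosis logistic parameters.
#' @export
default_predictor_specs <- function() {
  list(
    p_female = 0.17,
    p_noncauc = 0.17,
    mat_edu_probs = c(0.30, 0.28, 0.20, 0.13, 0.09),
    adx_intercept = 0.8,   # autism dx ~ plogis(a + b * z_css_t)
    adx_slope = 1.3,
    measures = list(
      measure_spec("viq",  c(2, 3, 5, 9), c(45, 50, 55, 62),
                   c(28, 29, 30, 31), w = -0.60, phi = 0.85),
      measure_spec("nviq", c(2, 3, 5, 9), c(70, 72, 74, 75),
                   c(22, 24, 26, 28), w = -0.60, phi = 0.85),
      measure_spec("css",  c(2, 3, 5, 9), c(6.5, 6.4, 6.2, 6.0),
                   2.4, w = 0.60, phi = 0.80),
      measure_spec("dls",  c(2, 3, 5, 9), c(68, 67, 66, 65),
                   c(10, 12, 13, 15), w = -0.50, phi = 0.80),
      measure_spec("irr",  c(9, 14, 17), c(6.5, 6.0, 5.5), 6,
                   w = 0.45, phi = 0.70),
      measure_spec("hyp",  c(9, 14, 17), c(10, 9, 8), 7,
                   w = 0.45, phi = 0.70),
      measure_spec("cbcl", c(9, 15), c(56, 55), 10, w = 0.50, phi = 0.70),
      measure_spec("sdq_emo", c(14, 17), 3, 2.5, w = 0.40, phi = 0.70),
      measure_spec("sdq_pro", c(14, 17), 6, 2.5, w = -0.40, phi = 0.70)
    )
  )
}

latent_column_names <- function(predictor_specs) {
  unlist(lapply(predictor_specs$measures, function(m)
    paste0(m$name, "_", m$ages)), use.names = FALSE)
}

#' Covariance of the latent predictor scores
#'
#' Closed-form covariance of the standardized latent scores `z_{m,t}` implied
#' by the shared-factor AR(1) construction: `cov = w_m * w_m'` across
#' measures and `w^2 + (1 - w^2) * phi^|i - i'|` within a measure (indices
#' count assessments). Used as the ground-truth input to [population_r2()].
#'
#' @param predictor_specs as from [default_predictor_specs()].
#' @return a named covariance matrix over all latent score columns.
#' @export
latent_covariance <- function(predictor_specs = default_predictor_specs()) {
  ms <- predictor_specs$measures
  cols <- latent_column_names(predictor_specs)
  idx <- do.call(rbind, lapply(ms, function(m)
    data.frame(measure = m$name, i = seq_along(m$ages), w = m$w,
               phi = m$phi)))
  p <- nrow(idx)
  S <- matrix(0, p, p, dimnames = list(cols, cols))
  for (a in seq_len(p)) for (b in seq_len(p)) {
    if (idx$measure[a] == idx$measure[b]) {
      S[a, b] <- idx$w[a]^2 +
        (1 - idx$w[a]^2) * idx$phi[a]^abs(idx$i[a] - idx$i[b])
    } else {
      S[a, b] <- idx$w[a] * idx$w[b]
    }
  }
  S
}

#' Default specifications for the 14 adult outcomes
#'
#' Eleven continuous outcomes (verbal and non-verbal IQ, daily-living
#' skills, autism symptom severity, hyperactivity, irritability, behavioral
#' problems, well-being, positive and negative affect, depression) and three
#' ordinal outcomes (independent living 1-3, friendships 0-3, work 1-7).
#' Loadings encode the qualitative predictability pattern the package's
#' validation machinery should recover: cognitive/adaptive outcomes load
#' heavily on their age-9 analogues, behavioral outcomes on adolescent
#' measures with modest strength, and well-being/affect/depression outcomes
#' are (nearly) pure noise.
#'
#' @return a named list of [outcome_spec()] objects.
#' @export
default_outcome_specs <- function() {
  sp <- list(
    outcome_spec("out_viq", "continuous", c(viq_9 = 42), 16, 62),
    outcome_spec("out_nviq", "continuous", c(nviq_9 = 41), 18, 70),
    outcome_spec("out_dls", "continuous", c(dls_9 = 21.5), 12.7, 60),
    outcome_spec("out_css", "continuous",
                 c(css_9 = 1.0, irr_14 = 0.5, hyp_14 = 0.4), 2.0, 5.5,
                 orientation = "higher_more_severe"),
    outcome_spec("out_hyp", "continuous", c(hyp_17 = 4.6), 5.3, 6,
                 orientation = "higher_more_severe"),
    outcome_spec("out_irr", "continuous", c(irr_14 = 4.4), 5.4, 6,
                 orientation = "higher_more_severe"),
    outcome_spec("out_abcl", "continuous", c(cbcl_15 = 3.2), 9, 53,
                 orientation = "higher_more_severe"),
    outcome_spec("out_wbq", "continuous", numeric(), 28, 190),
    outcome_spec("out_panas_p", "continuous", numeric(), 8, 28),
    outcome_spec("out_panas_n", "continuous", c(cbcl_15 = 1.6), 6.2, 17,
                 orientation = "higher_more_severe"),
    outcome_spec("out_bdi", "continuous", numeric(), 7, 6,
                 orientation = "higher_more_severe"),
    outcome_spec("out_living", "ordinal", c(dls_9 = 0.8, viq_9 = 0.5),
                 n_levels = 3, thresholds = c(-1.6, 1.4)),
    outcome_spec("out_friends", "ordinal", c(viq_9 = 0.9, dls_9 = 0.5),
                 n_levels = 4, thresholds = c(-1.7, -0.4, 0.9),
                 level_values = 0:3),
    outcome_spec("out_work", "ordinal",
                 c(viq_9 = 0.7, dls_9 = 0.5, css_9 = -0.3),
                 n_levels = 7,
                 thresholds = c(-2.0, -1.2, -0.5, 0.2, 0.9, 1.7))
  )
  names(sp) <- vapply(sp, `[[`, "", "name")
  sp
}

#' Specify the missingness mechanism
#'
#' Item-level missingness is independent Bernoulli per predictor cell.
#' Whole-wave dropout follows a missing-at-random discrete-time logistic
#' hazard on race and maternal education (dropout is monotone: once a
#' participant misses a wave they miss all later predictor waves). Adult
#' outcomes are additionally missing completely at random per outcome.
#'
#' @param item_missing_prob scalar or named per-column probability of an
#'   individual predictor cell being missing.
#' @param mar_coefficients named vector `c(intercept, noncauc, mat_edu)` of
#'   the per-wave dropout hazard `plogis(intercept + noncauc * I(non-Caucasian)
#'   + mat_edu * (maternal education - 1))`.
#' @param outcome_missing_prob scalar or named per-outcome probability.
#' @return an object of class `missingness_spec`.
#' @export
missingness_spec <- function(item_missing_prob = 0.03,
                             mar_coefficients = c(intercept = -2.5,
                                                  noncauc = 0.9,
                                                  mat_edu = -0.25),
                             outcome_missing_prob = 0.1) {
  if (any(item_missing_prob < 0 | item_missing_prob > 1) ||
      any(outcome_missing_prob < 0 | outcome_missing_prob > 1))
    stop("missingness probabilities must lie in [0, 1]")
  if (!all(c("intercept", "noncauc", "mat_edu") %in% names(mar_coefficients)))
    stop("`mar_coefficients` needs elements intercept, noncauc, mat_edu")
  structure(list(item_missing_prob = item_missing_prob,
                 mar_coefficients = mar_coefficients,
                 outcome_missing_prob = outcome_missing_prob),
            class = "missingness_spec")
}

#' Configure a synthetic cohort
#'
#' The defaults are the study conditions the package targets: 123
#' participants followed from toddlerhood to adulthood, the
#' [default_predictor_specs()] battery, the 14 [default_outcome_specs()]
#' adult outcomes, weak exchangeable residual correlation (0.2) across
#' outcomes, and missing-at-random dropout tied to race and maternal
#' education.
#'
#' @param n_participants cohort size.
#' @param seed integer RNG seed; generation is deterministic given the
#'   config, including the seed.
#' @param predictor_specs longitudinal predictor battery.
#' @param outcome_specs list of [outcome_spec()] objects.
#' @param residual_correlation K x K correlation matrix of outcome residuals
#'   (continuous on the residual scale, ordinal on the latent scale).
#' @param missingness a [missingness_spec()].
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 123,
                          seed = 1,
                          predictor_specs = default_predictor_specs(),
                          outcome_specs = default_outcome_specs(),
                          residual_correlation = NULL,
                          missingness = missingness_spec()) {
  stopifnot_scalar_number(n_participants, "n_participants", lower = 2)
  K <- length(outcome_specs)
  if (is.null(residual_correlation)) {
    residual_correlation <- matrix(0.2, K, K)
    diag(residual_correlation) <- 1
  }
  nm <- vapply(outcome_specs, `[[`, "", "name")
  names(outcome_specs) <- nm
  if (is.null(dimnames(residual_correlation)))
    dimnames(residual_correlation) <- list(nm, nm)
  check_correlation_matrix(residual_correlation)
  if (nrow(residual_correlation) != K)
    stop("`residual_correlation` must be K x K with K = number of outcomes")
  structure(list(n_participants = n_participants, seed = seed,
                 predictor_specs = predictor_specs,
                 outcome_specs = outcome_specs,
                 residual_correlation = residual_correlation,
                 missingness = missingness),
            class = "cohort_config")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a wide per-participant table: demographics, the longitudinal
#' predictor battery (shared severity factor plus AR(1) measure processes),
#' and the adult outcomes. Continuous outcomes are linear predictors plus
#' multivariate-normal residuals with the configured cross-outcome
#' correlation; ordinal outcomes threshold a unit-residual-variance latent
#' normal sharing that correlation. Ground truth (true coefficients, true
#' population R-squared per outcome, true residual correlation, latent
#' scores) is attached as the `"ground_truth"` attribute; no missingness is
#' applied here (see [apply_missingness()]).
#'
#' @param config a [cohort_config()].
#' @return a `cohort_table`: a `data.frame` with attributes `ground_truth`
#'   and `var_meta` (per-column role/type/timepoint).
#' @export
#' @examples
#' tab <- generate_cohort(cohort_config(n_participants = 50, seed = 7))
#' dim(tab)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- as.integer(config$n_participants)
  ps <- config$predictor_specs
  specs <- config$outcome_specs
  R <- config$residual_correlation
  K <- length(specs)
  load_cols <- latent_column_names(ps)
  n_load <- sum(vapply(specs, function(s) length(s$loadings), 0L))
  p_model <- 3 + length(load_cols)
  if (n < p_model)
    warning("n_participants < number of generator predictors; ",
            "downstream fits will be rank-deficient (overfitting regime)")

  with_seed(config$seed, {
    female <- rbinom(n, 1, ps$p_female)
    noncauc <- rbinom(n, 1, ps$p_noncauc)
    mat_edu <- sample.int(5, n, replace = TRUE, prob = ps$mat_edu_probs)
    g <- rnorm(n)

    Z <- matrix(NA_real_, n, length(load_cols),
                dimnames = list(NULL, load_cols))
    X <- list()
    for (m in ps$measures) {
      a <- rnorm(n)                      # stationary AR(1) on z-scale
      for (i in seq_along(m$ages)) {
        if (i > 1) a <- m$phi * a + sqrt(1 - m$phi^2) * rnorm(n)
        z <- m$w * g + sqrt(1 - m$w^2) * a
        col <- paste0(m$name, "_", m$ages[i])
        Z[, col] <- z
        X[[col]] <- m$means[i] + m$sds[i] * z
      }
    }
    # autism diagnosis indicator at the early-childhood waves, driven by
    # contemporaneous symptom severity
    for (age in c(2, 3, 5, 9)) {
      X[[paste0("adx_", age)]] <-
        rbinom(n, 1, plogis(ps$adx_intercept + ps$adx_slope *
                              Z[, paste0("css_", age)]))
    }

    sig <- vapply(specs, `[[`, 0, "residual_sd")
    Sigma <- diag(sig) %*% R %*% diag(sig)
    E <- MASS::mvrnorm(n, mu = rep(0, K), Sigma = Sigma)
    colnames(E) <- names(specs)

    Y <- list()
    for (s in specs) {
      lp <- if (length(s$loadings))
        drop(Z[, names(s$loadings), drop = FALSE] %*% s$loadings)
      else rep(0, n)
      if (s$kind == "continuous") {
        y <- s$intercept + lp + E[, s$name]
        if (!is.null(s$range_clip))
          y <- pmin(pmax(y, s$range_clip[1]), s$range_clip[2])
      } else {
        latent <- lp + E[, s$name]
        lev <- findInterval(latent, s$thresholds) + 1L
        y <- s$level_values[lev]
      }
      Y[[s$name]] <- y
    }
  })

  tab <- data.frame(id = seq_len(n), female = female, noncauc = noncauc,
                    mat_edu = mat_edu, X, Y, check.names = FALSE)

  truth <- list(
    config = config,
    latent_covariance = latent_covariance(ps),
    residual_correlation = R,
    coefficients = lapply(specs, `[[`, "loadings"),
    intercepts = vapply(specs, `[[`, 0, "intercept"),
    residual_sd = vapply(specs, `[[`, 0, "residual_sd"),
    thresholds = lapply(specs, `[[`, "thresholds"),
    population_r2 = vapply(specs, population_r2,
                           0, predictor_cov = latent_covariance(ps)),
    latent_scores = Z
  )
  meta <- cohort_var_meta(tab, ps, specs)
  structure(tab, ground_truth = truth, var_meta = meta,
            class = c("cohort_table", "data.frame"))
}

# per-column role / type / timepoint bookkeeping
cohort_var_meta <- function(tab, ps, specs) {
  nm <- names(tab)
  role <- rep("predictor", length(nm))
  type <- rep("continuous", length(nm))
  tp <- rep(NA_real_, length(nm))
  role[nm == "id"] <- "id"
  role[nm %in% c("female", "noncauc", "mat_edu")] <- "demographic"
  type[nm %in% c("female", "noncauc")] <- "binary"
  type[nm == "mat_edu"] <- "ordinal"
  type[grepl("^adx_", nm)] <- "binary"
  suffix <- suppressWarnings(as.numeric(sub("^.*_", "", nm)))
  tp[role == "predictor"] <- suffix[role == "predictor"]
  for (s in specs) {
    i <- which(nm == s$name)
    role[i] <- "outcome"
    type[i] <- s$kind
    tp[i] <- NA
  }
  data.frame(name = nm, role = role, type = type, timepoint = tp,
             stringsAsFactors = FALSE)
}

#' Ground truth of a synthetic cohort
#' @param table a `cohort_table`.
#' @return the ground-truth list recorded at generation.
#' @export
ground_truth <- function(table) attr(table, "ground_truth")

#' Per-column metadata of a cohort table
#' @param table a `cohort_table`.
#' @return data.frame with columns name, role, type, timepoint.
#' @export
var_meta <- function(table) attr(table, "var_meta")

#' @export
print.cohort_table <- function(x, ...) {
  meta <- var_meta(x)
  cat(sprintf("synthetic cohort: %d participants, %d predictors, %d outcomes\n",
              nrow(x), sum(meta$role %in% c("predictor", "demographic")),
              sum(meta$role == "outcome")))
  mv <- attr(x, "masked_values")
  if (!is.null(mv))
    cat(sprintf("missingness applied: %d masked cells\n", nrow(mv)))
  invisible(x)
}

#' Apply item missingness and MAR dropout to a cohort
#'
#' Blanks individual predictor cells with the configured per-column
#' probabilities, draws monotone whole-wave dropout from the logistic
#' missing-at-random model on race and maternal education, and blanks adult
#' outcomes with their per-outcome probabilities. The true values of every
#' blanked cell are retained in the `"masked_values"` attribute so that
#' imputation accuracy can be assessed.
#'
#' @param table a `cohort_table` from [generate_cohort()].
#' @param spec a [missingness_spec()].
#' @param seed integer seed (independent of the generation seed).
#' @return the cohort with `NA`s introduced; attributes preserved.
#' @export
apply_missingness <- function(table, spec, seed = 1) {
  stopifnot(inherits(spec, "missingness_spec"))
  meta <- var_meta(table)
  out <- table
  n <- nrow(out)
  pred_cols <- meta$name[meta$role == "predictor"]
  out_cols <- meta$name[meta$role == "outcome"]

  with_seed(seed, {
    # whole-wave monotone dropout (waves after the first assessment)
    waves <- sort(unique(meta$timepoint[meta$role == "predictor"]))
    waves <- waves[waves > min(waves)]
    co <- spec$mar_coefficients
    hazard <- plogis(co[["intercept"]] + co[["noncauc"]] * out$noncauc +
                       co[["mat_edu"]] * (out$mat_edu - 1))
    dropped <- rep(FALSE, n)
    for (w in waves) {
      dropped <- dropped | (runif(n) < hazard)
      cols <- meta$name[meta$role == "predictor" &
                          !is.na(meta$timepoint) & meta$timepoint == w]
      for (cl in cols) out[dropped, cl] <- NA
    }
    prob_for <- function(probs, cl) {
      if (is.null(names(probs))) probs[1]
      else if (cl %in% names(probs)) probs[[cl]] else 0
    }
    # item-level missingness on remaining predictor cells
    for (cl in pred_cols) {
      p <- prob_for(spec$item_missing_prob, cl)
      if (p > 0) out[runif(n) < p, cl] <- NA
    }
    # per-outcome missingness
    for (cl in out_cols) {
      p <- prob_for(spec$outcome_missing_prob, cl)
      if (p > 0) out[runif(n) < p, cl] <- NA
    }
  })

  masked <- which(is.na(as.matrix(out[setdiff(names(out), "id")])) &
                    !is.na(as.matrix(table[setdiff(names(table), "id")])),
                  arr.ind = TRUE)
  cols <- setdiff(names(out), "id")
  mv <- data.frame(row = masked[, 1],
                   column = cols[masked[, 2]],
                   value = mapply(function(r, c) table[[c]][r],
                                  masked[, 1], cols[masked[, 2]]))
  attr(out, "masked_values") <- mv
  out
}

#' Draw a priority profile over the ten outcome facets
#'
#' Simulates a completed priority questionnaire: non-negative integer points
#' over 10 facets summing to exactly 100, drawn Dirichlet-multinomial. Small
#' `concentration` gives spiky profiles (most points on a few facets); large
#' values approach the equal-priority profile of 10 points per facet.
#'
#' @param seed integer seed.
#' @param concentration positive Dirichlet concentration per facet.
#' @param labels facet labels (default [default_facet_labels()]).
#' @param total total points to allocate (default 100).
#' @return a [priority_profile()].
#' @export
generate_priority_profile <- function(seed = 1, concentration = 1,
                                      labels = default_facet_labels(),
                                      total = 100) {
  stopifnot_scalar_number(concentration, "concentration", lower = 1e-12)
  nf <- length(labels)
  pts <- with_seed(seed, {
    gam <- rgamma(nf, shape = concentration, rate = 1)
    if (all(gam == 0)) gam <- rep(1, nf)   # numerical underflow guard
    drop(rmultinom(1, total, gam / sum(gam)))
  })
  priority_profile(pts, labels)
}
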