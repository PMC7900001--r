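#' Pro-rate a partially completed scale
#'
#' A scale total is computed when at least 80% of its items are answered:
#' the mean of the answered items times the number of items. Below the 80%
#' completion threshold the scale is treated as missing.
#'
#' @param item_values numeric vector of item responses, `NA` for unanswered.
#' @param n_items number of items in the scale (default `length(item_values)`).
#' @param min_completion completion fraction required (default 0.8).
#' @return the pro-rated scale total, or `NA` if completion is insufficient.
#' @export
#' @examples
#' prorate_scale(c(2, 2, 2, 2, 2, 2, 2, 2, NA, NA))  # 8/10 answered -> 20
prorate_scale <- function(item_values, n_items = length(item_values),
                          min_completion = 0.8) {
  if (n_items < 1) stop("`n_items` must be at least 1")
  if (length(item_values) != n_items)
    stop("`item_values` must have length `n_items`")
  answered <- sum(!is.na(item_values))
  if (answered / n_items < min_completion) return(NA_real_)
  mean(item_values, na.rm = TRUE) * n_items
}

#' Predictor set for one model timepoint
#'
#' Encodes the most-recent-measurement rule: demographics at every
#' timepoint; verbal/non-verbal IQ, symptom severity, daily-living skills
#' and diagnosis from the child's own age up to 9 and frozen at age 9
#' thereafter; each behavioral measure represented only by its most recent
#' assessment; SDQ subscales appended only in the starred (`14*`, `17*`)
#' variants.
#'
#' @param timepoint_label one of `"2","3","5","9","14","14*","15","17","17*"`.
#' @param columns ordered predictor column names.
#' @param includes_sdq whether the set carries the SDQ subscales.
#' @return object of class `predictor_set_spec`.
#' @export
predictor_set_spec <- function(timepoint_label, columns,
                               includes_sdq = grepl("\\*$", timepoint_label)) {
  demog <- c("female", "noncauc", "mat_edu")
  if (!all(demog %in% columns))
    stop("demographics (female, noncauc, mat_edu) must be in every predictor set")
  if (anyDuplicated(columns)) stop("duplicate predictor columns")
  structure(list(timepoint_label = timepoint_label, columns = columns,
                 includes_sdq = includes_sdq),
            class = "predictor_set_spec")
}

#' Default predictor sets for the nine model timepoints
#'
#' @param sdq logical; include the starred variants' SDQ columns.
#' @return named list of [predictor_set_spec()] for labels
#'   2, 3, 5, 9, 14, 14*, 15, 17, 17*.
#' @export
default_predictor_sets <- function() {
  demog <- c("female", "noncauc", "mat_edu")
  core <- function(age) paste0(c("viq_", "nviq_", "css_", "dls_", "adx_"), age)
  sets <- list(
    "2"   = c(demog, core(2)),
    "3"   = c(demog, core(3)),
    "5"   = c(demog, core(5)),
    "9"   = c(demog, core(9), "irr_9", "hyp_9", "cbcl_9"),
    "14"  = c(demog, core(9), "irr_14", "hyp_14", "cbcl_9"),
    "14*" = c(demog, core(9), "irr_14", "hyp_14", "cbcl_9",
              "sdq_emo_14", "sdq_pro_14"),
    "15"  = c(demog, core(9), "irr_14", "hyp_14", "cbcl_15"),
    "17"  = c(demog, core(9), "irr_17", "hyp_17", "cbcl_15"),
    "17*" = c(demog, core(9), "irr_17", "hyp_17", "cbcl_15",
              "sdq_emo_17", "sdq_pro_17")
  )
  out <- lapply(names(sets), function(lb) predictor_set_spec(lb, sets[[lb]]))
  names(out) <- names(sets)
  out
}

#' Assemble the analysis matrix for one timepoint
#'
#' Selects exactly the spec's predictor columns (erroring with the column
#' name if one is absent) and, when an outcome is named, attaches its vector
#' (which may contain missing values; rows with a missing outcome are
#' excluded later, per outcome).
#'
#' @param table a cohort table (imputed or not).
#' @param spec a [predictor_set_spec()].
#' @param outcome optional outcome column name.
#' @return a list of class `analysis_matrix` with elements `x` (matrix),
#'   `y` (or `NULL`), `row_id`, `timepoint_label`, `outcome`.
#' @export
assemble_predictors <- function(table, spec, outcome = NULL) {
  stopifnot(inherits(spec, "predictor_set_spec"))
  absent <- setdiff(spec$columns, names(table))
  if (length(absent))
    stop("predictor column(s) not in table: ", paste(absent, collapse = ", "))
  x <- as.matrix(as.data.frame(table)[, spec$columns, drop = FALSE])
  storage.mode(x) <- "double"
  y <- NULL
  if (!is.null(outcome)) {
    if (!outcome %in% names(table)) stop("outcome column not in table: ", outcome)
    y <- table[[outcome]]
  }
  structure(list(x = x, y = y,
                 row_id = if ("id" %in% names(table)) table$id else
                   seq_len(nrow(x)),
                 timepoint_label = spec$timepoint_label, outcome = outcome),
            class = "analysis_matrix")
}

#' Standardize and orient outcomes onto a common scale
#'
#' Each outcome is centered, scaled to unit variance (sample SD, divisor
#' n - 1, computed over observed values) and multiplied by an orientation
#' sign so that all outcomes share the same direction of severity (default
#' convention: higher = less severe). The returned transform supports exact
#' inversion via [unstandardize_outcomes()].
#'
#' @param table a cohort table.
#' @param outcomes outcome column names.
#' @param orientation_map named vector of +1/-1 per outcome; by default
#'   derived from the cohort's outcome specs (`higher_more_severe` outcomes
#'   get sign -1).
#' @return list with `table` (standardized columns replaced) and
#'   `transform` (data.frame of mean, sd, sign per outcome).
#' @export
standardize_outcomes <- function(table, outcomes, orientation_map = NULL) {
  if (is.null(orientation_map)) {
    gt <- ground_truth(table)
    if (is.null(gt)) stop("supply `orientation_map` for non-synthetic tables")
    specs <- gt$config$outcome_specs
    orientation_map <- vapply(specs, function(s)
      if (s$orientation == "higher_more_severe") -1 else 1, 0)
  }
  tf <- data.frame(outcome = outcomes, mean = NA_real_, sd = NA_real_,
                   sign = NA_real_, stringsAsFactors = FALSE)
  out <- table
  for (i in seq_along(outcomes)) {
    nm <- outcomes[i]
    y <- table[[nm]]
    obs <- y[!is.na(y)]
    if (length(obs) < 2 || sd(obs) == 0)
      stop("outcome has fewer than 2 observed values or zero variance: ", nm)
    s <- orientation_map[[nm]] %||% 1
    tf$mean[i] <- mean(obs); tf$sd[i] <- sd(obs); tf$sign[i] <- s
    out[[nm]] <- s * (y - tf$mean[i]) / tf$sd[i]
  }
  list(table = out, transform = tf)
}

#' Invert [standardize_outcomes()]
#' @param table standardized table.
#' @param transform the transform returned by [standardize_outcomes()].
#' @return table on the original outcome scales.
#' @export
unstandardize_outcomes <- function(table, transform) {
  out <- table
  for (i in seq_len(nrow(transform))) {
    nm <- transform$outcome[i]
    out[[nm]] <- table[[nm]] / transform$sign[i] * transform$sd[i] +
      transform$mean[i]
  }
  out
}
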