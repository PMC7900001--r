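#' Optimism-corrected performance grid over outcomes and timepoints
#'
#' Runs the full internal-validation procedure for every outcome at every
#' model timepoint: nested leave-one-out cross-validated R-squared for
#' continuous outcomes (lasso by default, OLS available) and bootstrap
#' optimism-corrected generalized c-statistics for ordinal outcomes. Rows
#' with a missing outcome are excluded from that outcome's cell (predictors
#' must already be imputed). A failed cell is recorded as `NA` with a
#' logged diagnostic, never a silent zero.
#'
#' @param table imputed cohort table.
#' @param specs list of [predictor_set_spec()] covering the timepoints
#'   (default [default_predictor_sets()]).
#' @param outcome_meta data.frame with `name`, `kind` per outcome; defaults
#'   to the synthetic cohort's outcome specs.
#' @param seed integer seed (per-cell seeds are derived from it).
#' @param method continuous-outcome method, `"lasso"` or `"ols"`.
#' @param nested nested penalty re-selection (see [loocv_corrected_r2()]).
#' @param n_boot bootstrap repetitions for ordinal cells (default 40).
#' @return list of class `performance_grids` with elements `continuous` and
#'   `ordinal` (each a `performance_grid`: wide outcome x timepoint matrix
#'   of corrected performance plus long-format `records`), and `diagnostics`.
#' @export
run_validation_grid <- function(table, specs = default_predictor_sets(),
                                outcome_meta = NULL, seed = 1,
                                method = "lasso", nested = TRUE,
                                n_boot = 40) {
  if (is.null(outcome_meta)) {
    gt <- ground_truth(table)
    if (is.null(gt)) stop("supply `outcome_meta` for non-synthetic tables")
    specs_o <- gt$config$outcome_specs
    outcome_meta <- data.frame(
      name = vapply(specs_o, `[[`, "", "name"),
      kind = vapply(specs_o, `[[`, "", "kind"), stringsAsFactors = FALSE)
  }
  diag_log <- character()
  rec_cont <- list(); rec_ord <- list()
  cell <- 0L
  for (oi in seq_len(nrow(outcome_meta))) {
    nm <- outcome_meta$name[oi]
    kind <- outcome_meta$kind[oi]
    for (sp in specs) {
      cell <- cell + 1L
      cell_seed <- (seed + 7919L * cell) %% .Machine$integer.max
      am <- assemble_predictors(table, sp, outcome = nm)
      keep <- !is.na(am$y)
      res <- tryCatch({
        if (kind == "continuous") {
          r <- loocv_corrected_r2(am$x[keep, , drop = FALSE], am$y[keep],
                                  method = method, nested = nested,
                                  outcome = nm,
                                  timepoint_label = sp$timepoint_label)
          as.data.frame(r)
        } else {
          r <- bootstrap_corrected_c(am$x[keep, , drop = FALSE], am$y[keep],
                                     n_boot = n_boot, seed = cell_seed,
                                     outcome = nm,
                                     timepoint_label = sp$timepoint_label)
          as.data.frame(r)
        }
      }, error = function(e) {
        diag_log <<- c(diag_log, sprintf("%s @ %s: %s", nm,
                                         sp$timepoint_label,
                                         conditionMessage(e)))
        NULL
      })
      if (is.null(res)) {
        res <- data.frame(outcome = nm, timepoint = sp$timepoint_label,
                          n = sum(keep), stringsAsFactors = FALSE)
        if (kind == "continuous") {
          res$r2_apparent <- NA_real_; res$r2_corrected <- NA_real_
          res$method <- method
        } else {
          res$c_apparent <- NA_real_; res$c_corrected <- NA_real_
          res$n_boot <- n_boot; res$seed <- cell_seed
        }
      }
      if (kind == "continuous") rec_cont[[length(rec_cont) + 1L]] <- res
      else rec_ord[[length(rec_ord) + 1L]] <- res
    }
  }
  tp <- vapply(specs, `[[`, "", "timepoint_label")
  mk_grid <- function(recs, value_col) {
    if (!length(recs)) {
      return(structure(list(matrix = matrix(numeric(), 0, length(tp),
                                            dimnames = list(NULL, tp)),
                            records = data.frame()),
                       class = "performance_grid"))
    }
    long <- do.call(rbind, recs)
    outs <- unique(long$outcome)
    M <- matrix(NA_real_, length(outs), length(tp),
                dimnames = list(outs, tp))
    for (r in seq_len(nrow(long)))
      M[long$outcome[r], long$timepoint[r]] <- long[[value_col]][r]
    structure(list(matrix = M, records = long),
              class = "performance_grid")
  }
  structure(list(continuous = mk_grid(rec_cont, "r2_corrected"),
                 ordinal = mk_grid(rec_ord, "c_corrected"),
                 diagnostics = diag_log, seed = seed),
            class = "performance_grids")
}

#' @export
print.performance_grid <- function(x, ...) {
  print(round(x$matrix, 2))
  invisible(x)
}

#' @export
print.performance_grids <- function(x, ...) {
  cat("corrected R-squared (continuous outcomes):\n")
  print(x$continuous)
  cat("\ncorrected c-statistic (ordinal outcomes):\n")
  print(x$ordinal)
  if (length(x$diagnostics))
    cat("\nfailed cells:\n", paste(x$diagnostics, collapse = "\n"), "\n")
  invisible(x)
}

#' Minimum R-squared supporting model development at a given sample size
#'
#' The shrinkage-factor criterion for linear prediction models: the
#' R-squared at which `n` observations and `p` predictors give expected
#' shrinkage `S`, i.e. the solution of
#' `n = p / ((S - 1) * ln(1 - R2 / S))`, in closed form
#' `R2 = S * (1 - exp(-p / (n * (1 - S))))`. Monotone decreasing in `n`,
#' increasing in `p`. Models developed where the achievable R-squared falls
#' below this value risk overfitting.
#'
#' @param n sample size (must exceed `p`).
#' @param p number of candidate predictors (>= 1).
#' @param S target shrinkage factor in (0, 1), default 0.9.
#' @return minimum R-squared in (0, 1).
#' @export
#' @examples
#' riley_min_r2(123, 10)
riley_min_r2 <- function(n, p, S = 0.9) {
  stopifnot_scalar_number(S, "S", lower = 1e-9, upper = 1 - 1e-9)
  if (!is_wholenumber(p) || p < 1) stop("`p` must be an integer >= 1")
  if (!is_wholenumber(n) || n <= p) stop("`n` must be an integer > p")
  r2 <- S * (1 - exp(-p / (n * (1 - S))))
  if (!(r2 > 0 && r2 < 1)) stop("no solution in (0, 1)")
  r2
}

#' Predictive R-squared ceiling from test-retest reliability
#'
#' An outcome measured with test-retest intraclass correlation `icc` caps
#' the predictable variance: the ceiling is rendered as `icc^2`
#' (attenuation of the predictable signal by unreliability at both
#' measurement occasions).
#'
#' @param icc intraclass correlation(s) in `[0, 1]`.
#' @return R-squared ceiling(s).
#' @export
icc_ceiling <- function(icc) {
  if (any(icc < 0 | icc > 1)) stop("`icc` must lie in [0, 1]")
  icc^2
}

#' Write performance tables and figures
#'
#' Writes the long-format performance records as CSV, performance-vs-age
#' curves (with dashed test-retest ceiling lines at the configured ICCs on
#' the R-squared axis), and single-outcome / composite interval plots for
#' any supplied predictions.
#'
#' @param grids a [run_validation_grid()] result.
#' @param predictions optional named list of `composite_prediction`s.
#' @param out_dir output directory (created if needed).
#' @param icc ICC values for the ceiling lines (default 0.95, 0.8, 0.7).
#' @param format figure format, `"png"` or `"svg"`.
#' @return invisibly, the paths written.
#' @export
render_reports <- function(grids, predictions = NULL, out_dir,
                           icc = c(0.95, 0.8, 0.7), format = "png") {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character()
  wr <- function(df, file, cols) {
    path <- file.path(out_dir, file)
    if (!nrow(df)) df <- as.data.frame(stats::setNames(
      replicate(length(cols), numeric(), simplify = FALSE), cols))
    write.csv(df, path, row.names = FALSE)
    paths <<- c(paths, path)
  }
  wr(grids$continuous$records, "performance_continuous.csv",
     c("outcome", "timepoint", "n", "r2_apparent", "r2_corrected", "method"))
  wr(grids$ordinal$records, "performance_ordinal.csv",
     c("outcome", "timepoint", "n", "c_apparent", "c_corrected", "n_boot",
       "seed"))

  plot_grid <- function(grid, value_col, ylab, file, ceilings = NULL) {
    df <- grid$records
    if (!nrow(df)) return(invisible())
    df$age <- as.numeric(sub("\\*$", "", df$timepoint))
    df$sdq <- grepl("\\*$", df$timepoint)
    gg <- ggplot2::ggplot(
      df[!df$sdq, ],
      ggplot2::aes(x = .data$age, y = .data[[value_col]],
                   colour = .data$outcome)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "age at last included assessment", y = ylab) +
      ggplot2::theme_minimal()
    if (!is.null(ceilings))
      gg <- gg + ggplot2::geom_hline(yintercept = ceilings,
                                     linetype = "dashed", colour = "grey40")
    path <- file.path(out_dir, paste0(file, ".", format))
    ggplot2::ggsave(path, gg, width = 8, height = 5, dpi = 150)
    paths <<- c(paths, path)
  }
  plot_grid(grids$continuous, "r2_corrected",
            "optimism-corrected R-squared", "performance_continuous",
            ceilings = icc_ceiling(icc))
  plot_grid(grids$ordinal, "c_corrected",
            "optimism-corrected c-statistic", "performance_ordinal")

  if (!is.null(predictions) && length(predictions)) {
    pd <- do.call(rbind, lapply(names(predictions), function(nm) {
      p <- predictions[[nm]]
      data.frame(label = nm, point = p$point, se = p$se_pred,
                 lo = p$interval[1], hi = p$interval[2], level = p$level,
                 stringsAsFactors = FALSE)
    }))
    wr(pd, "predictions.csv", names(pd))
    gg <- ggplot2::ggplot(pd, ggplot2::aes(x = .data$point,
                                           y = .data$label)) +
      ggplot2::geom_point() +
      ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lo,
                                           xmax = .data$hi), height = 0.2) +
      ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
      ggplot2::labs(x = "standardized outcome (higher = less severe)",
                    y = NULL) +
      ggplot2::theme_minimal()
    path <- file.path(out_dir, paste0("predictions.", format))
    ggplot2::ggsave(path, gg, width = 7, height = 4, dpi = 150)
    paths <- c(paths, path)
  }
  invisible(paths)
}
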