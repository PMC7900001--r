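#' Write a cohort table to CSV with a JSON sidecar
#'
#' The CSV encodes missing entries as empty fields; the sidecar records the
#' generation ground truth (true coefficients, population R-squared,
#' residual correlation, thresholds) and an echo of the configuration, so a
#' written cohort can be round-tripped with [read_cohort()].
#'
#' @param table a `cohort_table`.
#' @param csv_path path of the CSV file.
#' @param sidecar_path path of the JSON sidecar (default: CSV path with a
#'   `.json` extension).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(table, csv_path,
                         sidecar_path = sub("\\.csv$", ".json", csv_path)) {
  write.csv(as.data.frame(table), csv_path, row.names = FALSE, na = "")
  gt <- ground_truth(table)
  side <- list(var_meta = var_meta(table))
  if (!is.null(gt)) {
    cfg <- gt$config
    side$ground_truth <- list(
      coefficients = gt$coefficients,
      intercepts = as.list(gt$intercepts),
      residual_sd = as.list(gt$residual_sd),
      thresholds = gt$thresholds,
      population_r2 = as.list(gt$population_r2),
      residual_correlation = gt$residual_correlation)
    side$config_echo <- list(n_participants = cfg$n_participants,
                             seed = cfg$seed)
  }
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(c(csv_path, sidecar_path))
}

#' Read a cohort table written by [write_cohort()]
#'
#' @param csv_path CSV path (empty fields read as missing).
#' @param sidecar_path optional JSON sidecar with column metadata.
#' @return a `cohort_table` (without regeneration ground truth; the sidecar
#'   metadata is reattached when available).
#' @export
read_cohort <- function(csv_path,
                        sidecar_path = sub("\\.csv$", ".json", csv_path)) {
  tab <- read.csv(csv_path, na.strings = "", check.names = FALSE)
  meta <- NULL
  if (file.exists(sidecar_path)) {
    side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    meta <- side$var_meta
  }
  structure(tab, var_meta = meta, class = c("cohort_table", "data.frame"))
}

#' Read a pipeline configuration file
#'
#' YAML or JSON; recognized fields are `n_participants`, `seed`,
#' missingness probabilities, validation options (`method`, `nested`,
#' `n_boot`), and priority points. Unspecified fields keep package
#' defaults.
#'
#' @param path configuration file (.yaml/.yml/.json).
#' @return a named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' Write the default configuration (all defaults echoed)
#' @param path output YAML path.
#' @return invisibly, `path`.
#' @export
write_default_config <- function(path) {
  ms <- missingness_spec()
  cfg <- list(
    n_participants = 123, seed = 1,
    missingness = list(item_missing_prob = ms$item_missing_prob,
                       mar_coefficients = as.list(ms$mar_coefficients),
                       outcome_missing_prob = ms$outcome_missing_prob),
    validation = list(method = "lasso", nested = TRUE, n_boot = 40),
    knn = list(k = 5),
    report = list(icc = c(0.95, 0.8, 0.7), format = "png"),
    composite = list(timepoint = "15", level = 0.95))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
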