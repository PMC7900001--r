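#' K-nearest-neighbor imputation
#'
#' Fills every missing cell of the selected columns from its k nearest rows.
#' Distance between two rows is Euclidean over the coordinates observed in
#' both, computed on column-standardized values and rescaled by
#' `(total columns / shared observed columns)` (a Gower-style correction for
#' partial overlap). Continuous cells are imputed as the neighbor mean;
#' binary/ordinal cells as the neighbor mode with ties broken toward the
#' lowest value. Distance ties are broken by row order, so the result is
#' deterministic. Imputation is intended to run on the whole dataset before
#' any validation split.
#'
#' @param table a data.frame / `cohort_table`.
#' @param k number of neighbors (default 5).
#' @param columns columns eligible for imputation and used in the distance;
#'   defaults to all predictor and demographic columns of a `cohort_table`
#'   (or all numeric columns otherwise).
#' @param discrete optional character vector of columns to impute by mode;
#'   by default, columns whose observed values are whole numbers with at
#'   most 10 distinct values.
#' @return the table with the selected columns complete; imputed cell
#'   positions recorded in the `"imputed_cells"` attribute.
#' @export
#' @examples
#' d <- data.frame(a = c(1, 1, 1, 1, 1, 1), b = c(2, 2, 2, 2, 2, NA))
#' knn_impute(d, k = 5)$b
knn_impute <- function(table, k = 5, columns = NULL, discrete = NULL) {
  meta <- var_meta(table)
  if (is.null(columns)) {
    columns <- if (!is.null(meta))
      meta$name[meta$role %in% c("predictor", "demographic")]
    else names(table)[vapply(table, is.numeric, TRUE)]
  }
  absent <- setdiff(columns, names(table))
  if (length(absent))
    stop("column(s) not in table: ", paste(absent, collapse = ", "))
  X <- as.matrix(as.data.frame(table)[, columns, drop = FALSE])
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  obs <- !is.na(X)
  zero_obs <- colSums(obs) == 0
  if (any(zero_obs))
    stop("column(s) with no observed values: ",
         paste(columns[zero_obs], collapse = ", "))
  if (is.null(discrete)) {
    discrete <- columns[vapply(seq_len(p), function(j) {
      v <- X[obs[, j], j]
      all(is_wholenumber(v)) && length(unique(v)) <= 10
    }, TRUE)]
  }
  if (!any(!obs)) {
    attr(table, "imputed_cells") <-
      data.frame(row = integer(), column = character())
    return(table)
  }

  mu <- colMeans(X, na.rm = TRUE)
  sg <- apply(X, 2, sd, na.rm = TRUE)
  sg[!is.finite(sg) | sg == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
  Z0 <- Z; Z0[!obs] <- 0

  need <- which(rowSums(!obs) > 0)
  filled <- X
  imputed <- list()
  for (i in need) {
    oi <- obs[i, ]
    # squared distance to every row over coordinates observed in both
    diffs <- sweep(Z0[, oi, drop = FALSE], 2, Z0[i, oi], "-")
    both <- obs[, oi, drop = FALSE]
    d2 <- rowSums((diffs^2) * both)
    shared <- rowSums(both)
    d2 <- ifelse(shared > 0, d2 * p / shared, Inf)
    d2[i] <- Inf
    for (j in which(!oi)) {
      donors <- which(obs[, j] & is.finite(d2))
      if (!length(donors))
        stop("no usable donor rows for column ", columns[j])
      ord <- donors[order(d2[donors], donors)]
      nb <- head(ord, k)
      v <- X[nb, j]
      filled[i, j] <- if (columns[j] %in% discrete) stat_mode_lowest(v)
      else mean(v)
      imputed[[length(imputed) + 1L]] <-
        data.frame(row = i, column = columns[j])
    }
  }
  out <- table
  for (j in seq_len(p)) out[[columns[j]]] <- filled[, j]
  attr(out, "imputed_cells") <- do.call(rbind, imputed)
  out
}
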