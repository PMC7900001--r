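# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so seeded generators do not clobber the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) & !is.na(x) & abs(x - round(x)) < tol
}

# symmetric, unit diagonal, eigenvalues >= -tol
check_correlation_matrix <- function(R, name = "residual_correlation",
                                     tol = 1e-8) {
  if (!is.matrix(R) || nrow(R) != ncol(R))
    stop(sprintf("`%s` must be a square matrix", name), call. = FALSE)
  if (max(abs(R - t(R))) > tol)
    stop(sprintf("`%s` must be symmetric", name), call. = FALSE)
  if (max(abs(diag(R) - 1)) > tol)
    stop(sprintf("`%s` must have a unit diagonal", name), call. = FALSE)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol)
    stop(sprintf("`%s` is not positive semidefinite (min eigenvalue %.3g)",
                 name, min(ev)), call. = FALSE)
  invisible(R)
}

# mode with ties broken toward the lowest value
stat_mode_lowest <- function(x) {
  x <- x[!is.na(x)]
  tab <- table(x)
  vals <- as.numeric(names(tab))
  vals[order(-as.integer(tab), vals)][1L]
}
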