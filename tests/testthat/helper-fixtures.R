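# shared fixture builders (everything generated in code, seeded)

# minimal cohort config with custom outcomes on iid-free latent structure
simple_config <- function(n, seed, outcome_specs, R = NULL) {
  cohort_config(n_participants = n, seed = seed,
                outcome_specs = outcome_specs,
                residual_correlation = R)
}

# continuous outcome loading only on the age-9 verbal-IQ latent score
loaded_outcome <- function(name, loading, residual_sd = 1,
                           orientation = "higher_less_severe") {
  outcome_spec(name, "continuous",
               loadings = stats::setNames(loading, "viq_9"),
               residual_sd = residual_sd, orientation = orientation)
}

# pure-noise continuous outcome
noise_outcome <- function(name, residual_sd = 1) {
  outcome_spec(name, "continuous", loadings = numeric(),
               residual_sd = residual_sd)
}

# design for regression tests: n x p standard normal
rand_design <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p,
         dimnames = list(NULL, paste0("x", seq_len(p))))
}

# y with exact population R2 given 3 active unit coefficients
signal_outcome <- function(X, r2, seed) {
  set.seed(seed + 1e6)
  b <- c(rep(1, 3), rep(0, ncol(X) - 3))
  if (r2 <= 0) return(rnorm(nrow(X)))
  s2 <- sum(b^2) * (1 - r2) / r2
  drop(X %*% b) + rnorm(nrow(X), sd = sqrt(s2))
}

# brute-force O(n^2) generalized c-statistic oracle
c_statistic_bruteforce <- function(scores, y) {
  conc <- 0; comp <- 0
  n <- length(y)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (y[i] == y[j]) next
    comp <- comp + 1
    hi <- if (y[i] > y[j]) i else j
    lo <- if (y[i] > y[j]) j else i
    if (scores[hi] > scores[lo]) conc <- conc + 1
    else if (scores[hi] == scores[lo]) conc <- conc + 0.5
  }
  conc / comp
}

# hand-built joint model object for closed-form interval algebra
manual_joint_model <- function(B, R, sigma, G, predictor_columns) {
  structure(list(B = B, R = R, sigma = sigma, G = G,
                 thresholds = stats::setNames(vector("list", nrow(B)),
                                              rownames(B)),
                 predictor_columns = predictor_columns,
                 outcome_meta = data.frame(name = rownames(B)),
                 psd_adjustment = 0, n = NA_integer_),
            class = "joint_outcome_model")
}
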