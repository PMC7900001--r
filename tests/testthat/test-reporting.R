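test_that("shrinkage-criterion minimum R2 matches a bisection oracle", {
  eqn <- function(r2, n, p, S) n - p / ((S - 1) * log(1 - r2 / S))
  set.seed(71)
  for (i in 1:100) {
    p <- sample(2:20, 1)
    n <- p + sample(10:500, 1)
    S <- runif(1, 0.6, 0.95)
    r2 <- riley_min_r2(n, p, S)
    oracle <- uniroot(eqn, c(1e-10, S - 1e-10), n = n, p = p, S = S,
                      tol = 1e-12)$root
    expect_equal(r2, oracle, tolerance = 1e-8)
  }
})

test_that("minimum R2 is monotone and vanishes asymptotically", {
  expect_lt(riley_min_r2(1e7, 10), 1e-4)
  expect_gt(riley_min_r2(123, 20), riley_min_r2(123, 10))
  expect_lt(riley_min_r2(500, 10), riley_min_r2(123, 10))
  expect_error(riley_min_r2(10, 10), "> p")
  expect_error(riley_min_r2(100, 10, S = 1.2), "S")
})

test_that("ICC measurement-reliability ceilings", {
  expect_equal(icc_ceiling(c(0.95, 0.8, 0.7)), c(0.95, 0.8, 0.7)^2)
  expect_error(icc_ceiling(1.2), "0, 1")
})

test_that("validation grid covers outcomes x timepoints deterministically", {
  tab <- generate_cohort(cohort_config(n_participants = 70, seed = 81))
  tab <- apply_missingness(tab, missingness_spec(0.02,
                                                 outcome_missing_prob = 0.1),
                           seed = 82)
  imp <- knn_impute(tab)
  om <- data.frame(name = c("out_viq", "out_bdi", "out_living"),
                   kind = c("continuous", "continuous", "ordinal"),
                   stringsAsFactors = FALSE)
  g1 <- run_validation_grid(imp, outcome_meta = om, seed = 4,
                            method = "ols", n_boot = 12)
  expect_equal(dim(g1$continuous$matrix), c(2, 9))
  expect_equal(dim(g1$ordinal$matrix), c(1, 9))
  # per-cell n equals the observed-outcome count, never the cohort size +
  recs <- g1$continuous$records
  for (nm in unique(recs$outcome))
    expect_true(all(recs$n[recs$outcome == nm] == sum(!is.na(tab[[nm]]))))
  expect_true(all(recs$n <= nrow(tab)))
  g2 <- run_validation_grid(imp, outcome_meta = om, seed = 4,
                            method = "ols", n_boot = 12)
  expect_identical(g1$continuous$records, g2$continuous$records)
  expect_identical(g1$ordinal$records, g2$ordinal$records)
})

test_that("well-predicted outcomes outrank noise outcomes in the grid", {
  tab <- generate_cohort(cohort_config(n_participants = 200, seed = 91))
  sets <- default_predictor_sets()
  am9 <- assemble_predictors(tab, sets[["9"]], outcome = "out_viq")
  r_viq <- loocv_corrected_r2(am9$x, am9$y)
  am9b <- assemble_predictors(tab, sets[["9"]], outcome = "out_bdi")
  r_bdi <- loocv_corrected_r2(am9b$x, am9b$y)
  am17 <- assemble_predictors(tab, sets[["17"]], outcome = "out_hyp")
  r_hyp <- loocv_corrected_r2(am17$x, am17$y)
  expect_gt(r_viq$r2_corrected, 0.6)
  expect_lt(r_bdi$r2_corrected, 0.15)
  expect_gt(r_hyp$r2_corrected, r_bdi$r2_corrected)
  expect_gt(r_viq$r2_corrected, r_hyp$r2_corrected)
})

test_that("ordinal discrimination improves from age 2 to age 9", {
  tab <- generate_cohort(cohort_config(n_participants = 200, seed = 93))
  sets <- default_predictor_sets()
  c2 <- with(assemble_predictors(tab, sets[["2"]], outcome = "out_living"),
             bootstrap_corrected_c(x, y, n_boot = 20, seed = 1))
  c9 <- with(assemble_predictors(tab, sets[["9"]], outcome = "out_living"),
             bootstrap_corrected_c(x, y, n_boot = 20, seed = 1))
  expect_gt(c9$c_corrected, c2$c_corrected)
  expect_gt(c9$c_corrected, 0.7)
})

test_that("reports render CSVs and figures, including empty grids", {
  dir_empty <- tempfile()
  empty <- structure(
    list(continuous = structure(list(matrix = matrix(numeric(), 0, 0),
                                     records = data.frame()),
                                class = "performance_grid"),
         ordinal = structure(list(matrix = matrix(numeric(), 0, 0),
                                  records = data.frame()),
                             class = "performance_grid"),
         diagnostics = character()),
    class = "performance_grids")
  expect_no_error(render_reports(empty, out_dir = dir_empty))
  csv <- file.path(dir_empty, "performance_continuous.csv")
  expect_true(file.exists(csv))
  expect_equal(nrow(read.csv(csv)), 0)   # header-only

  tab <- generate_cohort(cohort_config(n_participants = 60, seed = 95))
  om <- data.frame(name = c("out_viq", "out_living"),
                   kind = c("continuous", "ordinal"),
                   stringsAsFactors = FALSE)
  g <- run_validation_grid(tab, outcome_meta = om, seed = 4,
                           method = "ols", n_boot = 12)
  xn <- vapply(default_predictor_sets()[["15"]]$columns,
               function(cl) median(tab[[cl]]), 0)
  jm <- fit_joint_model(tab, default_predictor_sets()[["15"]])
  preds <- list(viq = predict_outcome_interval(jm, xn, "out_viq"))
  dir2 <- tempfile()
  paths <- render_reports(g, predictions = preds, out_dir = dir2)
  expect_true(file.exists(file.path(dir2, "performance_continuous.csv")))
  expect_true(file.exists(file.path(dir2, "performance_continuous.png")))
  expect_true(file.exists(file.path(dir2, "predictions.csv")))
})
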