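test_that("population_r2 matches the analytic variance decomposition", {
  expect_equal(population_r2(noise_outcome("y"), diag(2)), 0)
  expect_equal(population_r2(loaded_outcome("y", 1, residual_sd = 1),
                             matrix(1, dimnames = list("viq_9", "viq_9"))),
               0.5)
  sp <- outcome_spec("y", "continuous", c(a = 1, b = 1), residual_sd = 1)
  S <- matrix(c(1, .5, .5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(population_r2(sp, S), 3 / 4)  # b'Sb = 3
  expect_error(population_r2(sp, diag(3)), "conformable|lacks")
})

test_that("generation is deterministic given the config and seed", {
  cfg <- cohort_config(n_participants = 40, seed = 11)
  t1 <- generate_cohort(cfg)
  t2 <- generate_cohort(cfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # byte-identical after serialization
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(t1, f1); write_cohort(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(sub("csv$", "json", f1))[[1]]),
                   unname(tools::md5sum(sub("csv$", "json", f2))[[1]]))
})

test_that("null configuration yields no predictor-outcome association", {
  cfg <- simple_config(10000, 5,
                       list(noise_outcome("y1"), noise_outcome("y2")),
                       R = diag(2))
  tab <- generate_cohort(cfg)
  for (pred in c("viq_9", "css_2", "dls_5"))
    for (y in c("y1", "y2"))
      expect_lt(abs(cor(tab[[pred]], tab[[y]])), 0.05)
})

test_that("empirical R2 of the true linear predictor matches the target", {
  # Var(x'b) = 3 against residual variance 1 -> R2 = 0.75
  cfg <- simple_config(10000, 17,
                       list(loaded_outcome("y", sqrt(3), residual_sd = 1)))
  tab <- generate_cohort(cfg)
  gt <- ground_truth(tab)
  lp <- gt$latent_scores[, "viq_9"] * sqrt(3)
  r2_emp <- var(lp) / var(tab$y)
  expect_equal(gt$population_r2[["y"]], 0.75)
  expect_lt(abs(r2_emp - 0.75), 0.02)
})

test_that("default marginals respect instrument ranges when clipped", {
  specs <- default_outcome_specs()
  specs$out_viq$range_clip <- c(2, 139)
  specs$out_nviq$range_clip <- c(3, 133)
  tab <- generate_cohort(cohort_config(n_participants = 2000, seed = 3,
                                       outcome_specs = specs))
  expect_true(all(tab$out_viq >= 2 & tab$out_viq <= 139))
  expect_true(all(tab$out_nviq >= 3 & tab$out_nviq <= 133))
  expect_true(all(tab$out_living %in% 1:3))
  expect_true(all(tab$out_friends %in% 0:3))
  expect_true(all(tab$out_work %in% 1:7))
  # unclipped default is calibrated loosely: medians inside the ranges
  tab0 <- generate_cohort(cohort_config(n_participants = 2000, seed = 3))
  expect_gt(median(tab0$out_viq), 2); expect_lt(median(tab0$out_viq), 139)
})

test_that("ordinal marginals reproduce the threshold probabilities", {
  sp <- outcome_spec("yo", "ordinal", loadings = numeric(), n_levels = 3,
                     thresholds = c(-1, 0.5))
  tab <- generate_cohort(simple_config(20000, 23, list(sp),
                                       R = matrix(1, 1, 1)))
  target <- diff(c(0, pnorm(c(-1, 0.5)), 1))
  emp <- as.numeric(table(factor(tab$yo, levels = 1:3))) / 20000
  expect_true(all(abs(emp - target) < 0.02))
})

test_that("residual correlation of generated outcomes is recovered", {
  R <- matrix(c(1, .5, .2, .5, 1, .2, .2, .2, 1), 3, 3)
  specs <- list(loaded_outcome("y1", 1.5), loaded_outcome("y2", 0.8),
                noise_outcome("y3"))
  tab <- generate_cohort(simple_config(20000, 31, specs, R = R))
  gt <- ground_truth(tab)
  res <- sapply(c("y1", "y2", "y3"), function(nm) {
    b <- gt$coefficients[[nm]]
    lp <- if (length(b)) gt$latent_scores[, names(b), drop = FALSE] %*% b
    else 0
    tab[[nm]] - gt$intercepts[[nm]] - drop(lp)
  })
  Remp <- cor(res)
  expect_true(all(abs(Remp - R) < 0.03))
})

test_that("invalid residual correlation matrices are rejected", {
  bad <- matrix(c(1, .9, -.9, .9, 1, .9, -.9, .9, 1), 3, 3)  # not PSD
  specs <- list(noise_outcome("a"), noise_outcome("b"), noise_outcome("c"))
  expect_error(simple_config(50, 1, specs, R = bad), "positive semidefinite")
  asym <- diag(2); asym[1, 2] <- 0.3
  expect_error(simple_config(50, 1, specs[1:2], R = asym), "symmetric")
})

test_that("missingness: degenerate probabilities behave exactly", {
  tab <- generate_cohort(cohort_config(n_participants = 60, seed = 2))
  none <- apply_missingness(
    tab, missingness_spec(0, mar_coefficients = c(intercept = -50,
                                                  noncauc = 0, mat_edu = 0),
                          outcome_missing_prob = 0), seed = 9)
  attr(none, "masked_values") <- NULL
  expect_identical(as.data.frame(none), as.data.frame(tab))
  expect_identical(class(none), class(tab))
  all_irr14 <- apply_missingness(
    tab, missingness_spec(item_missing_prob = c(irr_14 = 1),
                          mar_coefficients = c(intercept = -20, noncauc = 0,
                                               mat_edu = 0),
                          outcome_missing_prob = 0), seed = 9)
  expect_true(all(is.na(all_irr14$irr_14)))
  expect_true(all(!is.na(all_irr14$viq_9)))
})

test_that("dropout is higher for the groups the MAR model targets", {
  # strongly positive race coefficient -> more missingness among
  # non-Caucasian participants, on average over seeds
  cfg <- cohort_config(n_participants = 300, seed = 41)
  tab <- generate_cohort(cfg)
  ms <- missingness_spec(item_missing_prob = 0,
                         mar_coefficients = c(intercept = -2, noncauc = 2,
                                              mat_edu = 0),
                         outcome_missing_prob = 0)
  rates <- sapply(1:100, function(s) {
    tm <- apply_missingness(tab, ms, seed = s)
    miss <- rowMeans(is.na(as.data.frame(tm)[, var_meta(tm)$role ==
                                               "predictor"]))
    c(mean(miss[tm$noncauc == 1]), mean(miss[tm$noncauc == 0]))
  })
  expect_gt(mean(rates[1, ]), mean(rates[2, ]))
  expect_gt(mean(rates[1, ] > rates[2, ]), 0.9)
})

test_that("priority profiles are valid Dirichlet-multinomial draws", {
  for (s in 1:20)
    expect_equal(sum(generate_priority_profile(s, 0.5)$facet_points), 100)
  # concentration -> infinity approaches the equal-priority profile
  near_uniform <- replicate(20, {
    p <- generate_priority_profile(sample.int(1e6, 1), 1e5)$facet_points
    max(abs(p - 10))
  })
  expect_lt(mean(near_uniform), 8)
  # small concentration concentrates points on few facets
  spiky <- mean(sapply(1:400, function(s)
    max(generate_priority_profile(s, 0.1)$facet_points) >= 30))
  expect_gt(spiky, 0.9)
  expect_identical(generate_priority_profile(7, 1)$facet_points,
                   generate_priority_profile(7, 1)$facet_points)
})
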