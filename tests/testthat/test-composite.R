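test_that("priority points map to outcome weights by matrix product", {
  mp <- default_facet_outcome_map()
  # uniform profile: each facet contributes 0.1 split over its outcomes
  w <- map_priorities_to_weights(priority_profile(rep(10, 10)), mp)
  expect_equal(sum(w), 1)
  expect_equal(unname(w["out_dls"]), 0.1)
  expect_equal(unname(w["out_viq"]), 0.05)   # cognitive facet split in two
  # all points on one facet wholly mapped to one outcome
  pts <- rep(0, 10); pts[which(default_facet_labels() == "work")] <- 100
  w1 <- map_priorities_to_weights(priority_profile(pts), mp)
  expect_equal(unname(w1["out_work"]), 1)
  expect_equal(sum(w1), 1)
  # 60/40 over two facets, each split evenly over 2 outcomes
  M <- matrix(0, 2, 4, dimnames = list(c("f1", "f2"), paste0("o", 1:4)))
  M[1, 1:2] <- 0.5; M[2, 3:4] <- 0.5
  m2 <- facet_outcome_map(M)
  p2 <- priority_profile(c(60, 40), labels = c("f1", "f2"))
  expect_equal(unname(map_priorities_to_weights(p2, m2)),
               c(0.3, 0.3, 0.2, 0.2))
})

test_that("profile and map validation", {
  expect_error(priority_profile(c(rep(20, 5), rep(1, 5))), "at most 100")
  expect_error(priority_profile(c(-1, rep(11, 9))), "non-negative")
  bad <- matrix(0.4, 2, 2)
  expect_error(facet_outcome_map(bad), "sum to 1")
})

test_that("one-hot weights reduce the composite to the single outcome", {
  tab <- generate_cohort(cohort_config(n_participants = 150, seed = 61))
  jm <- fit_joint_model(tab, default_predictor_sets()[["15"]])
  xn <- vapply(jm$predictor_columns, function(cl) median(tab[[cl]]), 0)
  for (nm in c("out_viq", "out_bdi", "out_living")) {
    single <- predict_outcome_interval(jm, xn, nm)
    w <- stats::setNames(rep(0, nrow(jm$B)), rownames(jm$B)); w[nm] <- 1
    comp <- predict_composite_interval(jm, xn, w)
    expect_equal(comp$point, single$point)
    expect_equal(comp$se_pred, single$se_pred)
    expect_equal(comp$interval, single$interval)
  }
  # composite point equals the weighted sum of single-outcome points
  set.seed(62); w <- runif(nrow(jm$B)); names(w) <- rownames(jm$B)
  singles <- vapply(rownames(jm$B), function(nm)
    predict_outcome_interval(jm, xn, nm)$point, 0)
  expect_equal(predict_composite_interval(jm, xn, w)$point,
               sum(w * singles))
})

test_that("identity residual correlation gives the 1/K closed form", {
  K <- 5; p <- 3; n <- 40
  set.seed(63)
  X1 <- cbind(1, matrix(rnorm(n * p), n, p))
  G <- solve(crossprod(X1))
  B <- matrix(rnorm(K * (p + 1)), K, p + 1,
              dimnames = list(paste0("o", 1:K), colnames(X1)))
  jm <- manual_joint_model(B, diag(K), stats::setNames(rep(1, K),
                                                       rownames(B)),
                           G, paste0("x", 1:p))
  xn <- stats::setNames(rnorm(p), paste0("x", 1:p))
  lev <- drop(t(c(1, xn)) %*% G %*% c(1, xn))
  w <- rep(1 / K, K)
  pc <- predict_composite_interval(jm, xn, w)
  expect_equal(pc$se_pred^2, (1 + lev) / K, tolerance = 1e-12)
  # the interval narrows as K grows under independence
  se_k <- vapply(2:K, function(kk) {
    jmk <- manual_joint_model(B[1:kk, , drop = FALSE], diag(kk),
                              stats::setNames(rep(1, kk),
                                              rownames(B)[1:kk]),
                              G, paste0("x", 1:p))
    predict_composite_interval(jmk, xn, rep(1 / kk, kk))$se_pred
  }, 0)
  expect_true(all(diff(se_k) < 0))
})

test_that("intercept-only prediction interval has the textbook variance", {
  n <- 25; sig <- 1.7
  B <- matrix(0.4, 1, 1, dimnames = list("o1", "(Intercept)"))
  jm <- manual_joint_model(B, matrix(1, 1, 1), c(o1 = sig),
                           matrix(1 / n, 1, 1), character())
  p <- predict_outcome_interval(jm, numeric(0), "o1")
  expect_equal(p$se_pred^2, sig^2 * (1 + 1 / n), tolerance = 1e-12)
  expect_equal(unname(p$interval["hi"] - p$interval["lo"]),
               2 * qnorm(0.975) * p$se_pred)
  expect_lt(p$interval["lo"], p$point); expect_gt(p$interval["hi"], p$point)
})

test_that("interval width is monotone in residual scale and leverage", {
  K <- 3; p <- 2
  set.seed(64)
  X1 <- cbind(1, matrix(rnorm(60 * p), 60, p))
  G <- solve(crossprod(X1))
  B <- matrix(rnorm(K * (p + 1)), K, p + 1,
              dimnames = list(paste0("o", 1:K), colnames(X1)))
  R <- diag(K); R[R == 0] <- 0.2
  w <- c(0.5, 0.3, 0.2)
  base_sig <- c(o1 = 0.5, o2 = 0.8, o3 = 1)
  xn <- stats::setNames(c(0.3, -1), paste0("x", 1:p))
  se0 <- predict_composite_interval(
    manual_joint_model(B, R, base_sig, G, paste0("x", 1:p)), xn, w)$se_pred
  for (j in 1:K) {
    sig2 <- base_sig; sig2[j] <- sig2[j] * 1.5
    se2 <- predict_composite_interval(
      manual_joint_model(B, R, sig2, G, paste0("x", 1:p)), xn, w)$se_pred
    expect_gt(se2, se0)
  }
  xfar <- xn * 10                               # higher leverage
  sef <- predict_composite_interval(
    manual_joint_model(B, R, base_sig, G, paste0("x", 1:p)), xfar,
    w)$se_pred
  expect_gt(sef, se0)
})

test_that("weights on unpredictable outcomes widen the interval", {
  specs <- list(loaded_outcome("good1", 2, residual_sd = 0.8),
                loaded_outcome("good2", 1.5, residual_sd = 0.9),
                noise_outcome("bad1"), noise_outcome("bad2"))
  wins <- sapply(1:20, function(s) {
    tab <- generate_cohort(simple_config(120, 800 + s, specs, R = diag(4)))
    jm <- fit_joint_model(tab, default_predictor_sets()[["9"]])
    xn <- vapply(jm$predictor_columns, function(cl) median(tab[[cl]]), 0)
    wp <- c(good1 = .5, good2 = .5, bad1 = 0, bad2 = 0)
    wn <- c(good1 = 0, good2 = 0, bad1 = .5, bad2 = .5)
    predict_composite_interval(jm, xn, wn)$se_pred >
      predict_composite_interval(jm, xn, wp)$se_pred
  })
  expect_true(all(wins))
})
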