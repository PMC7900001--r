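# outcomecast

Clinical prediction modeling of heterogeneous, multi-facet adult outcomes
from childhood and adolescent measures — with honest, optimism-corrected
estimates of how predictable each facet actually is, and prediction
intervals for personalized composite outcomes weighted by elicited
priorities.

## The problem

Children referred to autism services are followed with repeated
assessments (verbal and non-verbal IQ, autism symptom severity, adaptive
daily-living skills, later behavioral and emotional measures), and their
adult outcomes span cognition, behavior, mental health, well-being, and
social functioning. Some of those adult facets are highly predictable from
mid-childhood; others are essentially unpredictable at any age. In small
developmental cohorts, apparent (resubstitution) model performance grossly
overstates what a model would achieve in new children, so internal
validation must correct for optimism. And because "a good adult outcome"
differs between families, single-number summaries should be able to weight
outcome facets by the priorities of the people involved.

`outcomecast` implements this pipeline end to end:

- **Continuous outcomes** — lasso regression (coordinate descent on the
  objective `(1/2n)·RSS + λ·Σ|βj|`, unpenalized intercept, internally
  standardized predictors), with the penalty chosen to minimize
  leave-one-out cross-validated MSE, and performance reported as
  **optimism-corrected R²** from a fully nested LOOCV: for every held-out
  row the whole procedure, including penalty selection, is refit on the
  remaining rows. Corrected R² can legitimately be negative.
- **Ordinal outcomes** — proportional-odds (cumulative logit) regression
  fit by maximum likelihood, scored by the **generalized c-statistic**
  (concordance over pairs with different outcome levels, ties counting
  one-half), corrected by **Harrell's bootstrap** (40 repetitions by
  default).
- **Composite outcomes** — a joint model of all standardized outcomes with
  correlated residuals (ordinal outcomes on a unit-variance latent probit
  scale; residual correlations assembled from Pearson / polyserial /
  polychoric estimates and projected to the nearest PSD correlation
  matrix). For a priority profile (up to 100 points over 10 facets mapped
  to outcome weights `w`) the composite prediction for a new child `x` is
  `w'(Bx)` with prediction variance `(1 + x'Gx)·(w'R̃w)`, where
  `G = (X'X)⁻¹` carries parameter uncertainty and `R̃` is the residual
  covariance. Weakly correlated residuals make composites *tighter* than
  their components.
- **Preprocessing** — pro-rating of partially completed scales (80%
  completion rule), per-timepoint predictor sets under the
  most-recent-measurement rule, deterministic 5-nearest-neighbor
  imputation (standardized Euclidean distance over shared observed
  coordinates, Gower-style rescaling), outcome standardization and reverse
  scoring.
- **Synthetic cohorts** — because the motivating cohort data are sensitive
  and not shareable, a seeded generator produces cohorts with the same
  statistical structure (longitudinal shared-factor AR(1) predictors, 14
  adult outcomes with configurable population R², cross-outcome residual
  correlation, missing-at-random dropout tied to race and maternal
  education) and records the full ground truth, so every stage is testable.
- **Planning** — the shrinkage-factor minimum-R² criterion
  (`riley_min_r2`) and test-retest ICC ceilings on achievable R².

## Worked example

```r
library(outcomecast)

# a synthetic cohort at the default study conditions: 123 participants,
# waves at ages 2-17 plus adulthood, MAR dropout, 14 adult outcomes
cohort <- generate_cohort(cohort_config(n_participants = 123, seed = 7))
cohort <- apply_missingness(cohort, missingness_spec(), seed = 8)
cohort
#> synthetic cohort: 123 participants, 35 predictors, 14 outcomes
#> missingness applied: 965 masked cells

imputed <- knn_impute(cohort, k = 5)   # whole-table, before any CV split

# how well is adult verbal IQ predicted from the age-9 battery?
am <- assemble_predictors(imputed, default_predictor_sets()[["9"]],
                          outcome = "out_viq")
keep <- !is.na(am$y)
loocv_corrected_r2(am$x[keep, ], am$y[keep], method = "lasso",
                   outcome = "out_viq", timepoint_label = "9")
#> out_viq | 9 | n = 111 | R2 apparent = 0.733, corrected = 0.720 (lasso)

# ordinal outcome: independent living, bootstrap-corrected concordance
am2 <- assemble_predictors(imputed, default_predictor_sets()[["9"]],
                           outcome = "out_living")
bootstrap_corrected_c(am2$x[!is.na(am2$y), ], am2$y[!is.na(am2$y)],
                      n_boot = 40, seed = 9,
                      outcome = "out_living", timepoint_label = "9")
#> out_living | 9 | n = 108 | c apparent = 0.837, corrected = 0.777 (40 boot)

# is that R2 above the overfitting floor for this sample size?
riley_min_r2(123, 10)        # minimum developable R2 at n=123, 10 predictors
#> [1] 0.5008303

# composite prediction for a child at the 25th centile of the predictors,
# weighted by a simulated parent's priority questionnaire
all_imp <- knn_impute(imputed, k = 5,
                      columns = setdiff(names(imputed), "id"))
jm <- fit_joint_model(all_imp, default_predictor_sets()[["15"]])
x_child <- vapply(jm$predictor_columns,
                  function(cl) quantile(all_imp[[cl]], 0.25, names = FALSE), 0)
w <- map_priorities_to_weights(
  generate_priority_profile(seed = 10, concentration = 0.5))

predict_outcome_interval(jm, x_child, "out_viq")
#> out_viq: -0.590 [-1.695, 0.516] (95% prediction interval)
predict_composite_interval(jm, x_child, w)
#> composite: -0.117 [-0.880, 0.646] (95% prediction interval)
```

Outcomes are on the standardized scale with higher = less severe impact, so
this child's predicted verbal IQ is about half an SD below the cohort mean,
with a wide individual-level interval; the priority-weighted composite is
tighter than the single outcome because prediction errors across facets are
only weakly correlated.

The same pipeline is scriptable from a shell (`inst/cli/outcomecast`) with
the verbs `simulate`, `impute`, `validate`, `composite`, `report`, `all`,
and global `--seed` / `--config` / `--out` options.

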