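---
title: "Predicting multi-facet adult outcomes: models, validation, and priority-weighted composites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting multi-facet adult outcomes: models, validation, and priority-weighted composites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`outcomecast` develops and internally validates prediction models that map
childhood and adolescent assessments of children referred to autism
services onto 14 heterogeneous adult outcomes, and turns those models into
personalized composite predictions weighted by elicited priorities. This
vignette is the package's account of its statistical methods: the models
and their assumptions, the tunable parameters and why their defaults are
what they are, what the synthetic-cohort generator does and does not
emulate, the numerical choices, and the limitations.

## 1. The prediction problem

One row per participant; predictors are grouped into nine model
"timepoints" (labels 2, 3, 5, 9, 14, 14\*, 15, 17, 17\*) under a
most-recent-measurement rule:

* demographics (sex, race, maternal education 1–5) enter at every
  timepoint;
* verbal IQ, non-verbal IQ, autism symptom severity (ADOS Calibrated
  Severity Score), daily-living skills (Vineland standard score) and a
  concurrent autism-diagnosis indicator enter at the child's own age up to
  9 and are frozen at their age-9 values thereafter (no later childhood
  assessments of these exist before adulthood);
* irritability and hyperactivity (ABC subscales) and total behavior
  problems (CBCL) join at age 9 and are updated at 14 (15 for the CBCL)
  and 17;
* teacher-rated SDQ emotion and prosocial subscales are appended only in
  the starred variants 14\* and 17\*.

Eleven adult outcomes are continuous (verbal/non-verbal IQ, daily-living
skills, symptom severity, hyperactivity, irritability, behavioral
problems, well-being, positive and negative affect, depression) and three
are ordinal (independent living 1–3, friendships 0–3, work 1–7).

A separate model is fit for each outcome at each timepoint. Participants
missing a given outcome are excluded from that outcome's model; missing
*predictors* are imputed once, on the whole table, before any validation
split (section 4).

## 2. Continuous outcomes: lasso and nested LOOCV

`fit_lasso()` minimizes

$$\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i'\beta)^2 + \lambda \|\beta\|_1$$

by cyclic coordinate descent with soft-thresholding, an unpenalized
intercept, and predictors standardized internally to population (divisor
\(n\)) unit variance; coefficients are reported on the original scale.
Working on sufficient statistics \((X'X, X'y)\) makes each leave-one-out
fold a rank-one downdate costing \(O(p^2)\), which is what keeps the fully
nested cross-validation below practical. Convergence is declared when no
coefficient moves by more than `tol` (default `1e-7`); the objective is
convex, so the recorded objective trace is non-increasing by construction
and the iteration cap signals a bug rather than divergence. On
well-conditioned data the \(\lambda = 0\) solution matches OLS, at
\(\lambda \ge \lambda_{\max} = \max_j |n^{-1} x_j'(y-\bar y)|\) all slopes
are exactly zero, and for orthonormal designs the solution is exactly the
soft-threshold of the OLS coefficients — all verified in the test suite,
along with agreement with glmnet to `1e-6`.

The penalty grid is 100 log-spaced values from \(\lambda_{\max}\) down to
\(0.001\,\lambda_{\max}\) (the common default geometry for penalized
regression); `select_lambda_loocv()` picks the grid value minimizing the
leave-one-out MSE, breaking ties toward the larger penalty (the sparser
model).

**Optimism correction.** `loocv_corrected_r2()` reports

$$R^2_{\text{corrected}} = 1 - \frac{\sum_i (y_i - \hat y_{-i})^2}
                                    {\sum_i (y_i - \bar y)^2},$$

where \(\hat y_{-i}\) comes from refitting the *entire* procedure —
including re-selecting \(\lambda\) by an inner LOOCV — on the \(n-1\)
remaining rows. Re-selecting inside every fold avoids the information
leakage of tuning on the full sample; a non-nested mode (`nested = FALSE`)
is available for comparison. The denominator uses the full-sample mean
rather than fold-specific means (switchable in principle; the full-sample
convention keeps the statistic interpretable as a fraction of total
variance). Negative corrected values are meaningful: the model predicts
worse than the cohort mean.

Two properties of this estimator matter when reading recovery simulations.
First, it estimates the out-of-sample \(R^2\) *of the fitted procedure*,
which at \(n = 120\) with 10 candidate predictors sits below the
generative population \(R^2\) by roughly \((1-R^2)\,p/n\) plus lasso
shrinkage — about 0.04 at population \(R^2 = 0.5\). Second, its
per-replicate sampling SD at that size is 0.06–0.07, so individual
replicates scatter well beyond ±0.10 around the population value even when
the estimator is working exactly as intended. The acceptance suite states
both the mean- and replicate-level checks at their nominal tolerances and
the \(R^2=0.5\) replicate-level check is expected to fail for this
inherent statistical reason, not an implementation one.

## 3. Ordinal outcomes: proportional odds, c-statistic, bootstrap

`fit_propodds()` fits the cumulative model
\(P(Y \le j \mid x) = F(\theta_j - x'\beta)\) (logistic \(F\) for
reporting; probit for the joint latent model of section 5) by maximum
likelihood. Thresholds are kept strictly increasing by optimizing
\((\theta_1, \log(\theta_2-\theta_1), \dots)\) unconstrained (BFGS with
analytic gradients, followed by a safeguarded Newton polish in the natural
parameterization); convergence requires the gradient max-norm below
`1e-6`. Levels absent from the data are collapsed away, keeping the model
dimension well defined; complete separation is flagged rather than
silently returned. No penalization is used for ordinal outcomes: with few
events in some categories, cross-validating a penalty is not feasible, so
the ordinal models stay unpenalized by design.

Discrimination is the generalized c-statistic: over all pairs with
different outcome levels, the proportion where the higher-outcome member
has the higher score \(x'\hat\beta\), ties counting one-half. The
implementation aggregates Mann–Whitney rank sums per level pair
(\(O(J^2 n \log n)\)) and is tested to agree *exactly* with brute-force
pair enumeration, and to be invariant to strictly increasing score
transforms. The linear predictor is the natural concordance score because
it orders the latent expectation.

`bootstrap_corrected_c()` implements Harrell's optimism bootstrap with a
default of 40 repetitions: each resample refits the model; its optimism is
its c on the resample minus its c on the original data; the corrected c
subtracts the mean optimism from the apparent c. Resamples missing an
outcome level are redrawn (up to 100 times, then that repetition is
skipped with a message) — redrawing rather than collapsing levels keeps
the model dimension constant across repetitions. Forty repetitions is a
deliberately small default inherited from the analysis this package
operationalizes; it is configurable, and stochastic properties in the test
suite are established over many independent seeds rather than by inflating
`n_boot`.

## 4. Preprocessing

**Pro-rating.** A partially completed scale is pro-rated to
`mean(answered) * n_items` when at least 80% of items are answered, else
missing.

**KNN imputation.** `knn_impute()` uses \(k = 5\) neighbors. Distance
between rows is Euclidean over the coordinates observed in both rows,
computed on column-standardized values, and rescaled by
(total columns / shared observed columns) — the Gower-style convention for
partial overlap. Continuous cells take the neighbor mean; binary/ordinal
cells the neighbor mode with ties broken toward the lowest value; distance
ties break by row order, so imputation is fully deterministic. Imputation
runs on the whole dataset before any validation split; this mirrors the
original analysis and is a known, mild source of optimism (the held-out
row's predictors may have been imputed using all rows) accepted for
comparability.

**Standardization.** Outcomes are centered and scaled to unit variance
using the sample SD (divisor \(n-1\); the convention is recorded in the
returned transform and round-trips exactly), and reverse-scored where
needed so all outcomes share one severity direction. Text and figure
conventions for "which direction is severe" genuinely conflict in this
literature; the package default is **higher = less severe**, exposed as an
orientation map so either convention is one switch away.

## 5. The joint outcome model and composite intervals

Single-outcome validation models (sections 2–3) quantify *how predictable*
each facet is. For personalized composites the package fits one joint
model at a chosen timepoint: every outcome regressed on the same predictor
set, continuous outcomes by least squares on the standardized scale,
ordinal outcomes by cumulative *probit* regression on a unit-residual-
variance latent scale. With an identical regressor set across outcomes,
these outcome-wise fits coincide with the weighted-least-squares solution
of the corresponding structural equation model with correlated residuals,
so the package uses the equivalent two-stage estimator: after the fits,
the residual correlation matrix \(R\) is assembled pairwise — Pearson for
continuous–continuous, and *conditional* polyserial / polychoric MLEs for
pairs involving ordinal outcomes (the latent correlation given each
outcome's fitted regression, profiled over a 1-D likelihood; the bivariate
normal rectangle probabilities come from a vectorized Gauss–Legendre
evaluation of the single-integral identity for \(\Phi_2\), accurate to
about `1e-10` for \(|\rho| \le 0.99\) and tested against an independent
implementation). If the assembled \(R\) is indefinite it is projected to
the nearest PSD correlation matrix and the Frobenius adjustment distance
is recorded (zero in all tested scenarios).

For a new child with predictor row \(x\) (intercept prepended), outcome
\(k\) has point prediction \(x'B_k\) and prediction variance

$$\operatorname{se}^2_k = \sigma_{kk}\,(1 + x'(X'X)^{-1}x),$$

combining residual variance with parameter-estimation uncertainty through
the training design; \(\sigma_{kk} = 1\) on the ordinal latent scale and
\(\widehat{RSS}/(n-p)\) on the standardized continuous scale. A priority
profile (integer points summing to at most 100 over ten facets) maps to
outcome weights \(w = (\text{points}/100)' M\) through a facet-to-outcome
share matrix \(M\) whose rows sum to one; the default \(M\) distributes
each facet uniformly over a curated outcome subset and is fully
configurable (the mapping used with the original questionnaire is not
publicly available, so the default is a documented synthetic stand-in).
The composite prediction is

$$w'(Bx) \;\pm\; z_{0.975}\sqrt{(1 + x'(X'X)^{-1}x)\; w'\tilde R w},$$

with \(\tilde R = D R D\) the residual covariance (\(D\) the residual
SDs). One-hot weights reduce this *exactly* to the single-outcome
interval; with identity \(R\) and equal weights the variance is
\((1+x'Gx)/K\), so composites of many weakly correlated facets are
necessarily tighter than their components — the quantitative version of
"an extreme outcome in one facet does not imply an extreme outcome in
another".

Three conventions deserve explicit statement. (i) Ordinal components enter
the composite on the latent probit scale — the only coherent reading of a
normal variable underlying an ordinal outcome — with the fitted thresholds
attached for interpretation. (ii) The latent location is not identified,
so ordinal predictions are centered at the training mean of the fitted
linear predictor, putting them on a mean-zero scale comparable to the
standardized continuous outcomes. (iii) Composite *point* predictions use
the unpenalized joint fit (matching the SEM estimator), not the lasso
fits; the interval machinery is agnostic and a config option can
substitute lasso points.

Empirical coverage of the nominal 95% composite intervals is verified on
cohorts generated from the model's own assumptions (20 seeds × 2,000 new
individuals in the acceptance suite; observed coverage ≈ 95–96%). Coverage
is measured on continuous components: the latent value of an ordinal
outcome is unobservable even in simulation up to the centering convention,
and its interval algebra is identical.

## 6. The synthetic-cohort generator

Real cohorts of this kind cannot be shared, so `generate_cohort()` draws
cohorts with the statistical structure the analysis assumes, plus full
ground truth (true coefficients, true population \(R^2\) per outcome, true
residual correlation, latent scores) for recovery testing.

* **Predictors.** Each repeated measure follows a shared-factor AR(1)
  construction on the z-scale: \(z_{m,t} = w_m g + \sqrt{1-w_m^2}\,
  a_{m,t}\), with \(g\) a participant-level severity factor (loadings
  negative for skills, positive for symptom/behavior measures) and
  \(a_{m,t}\) a stationary AR(1) across that measure's assessments. This
  gives constant cross-measure correlations \(w_m w_{m'}\), within-measure
  autocorrelation \(w_m^2 + (1-w_m^2)\phi^{|\Delta|}\), and — because
  adult outcomes load on age-9 (and adolescent) scores — the qualitative
  pattern that age-9 measures predict their adult analogues strongly.
  Marginal means and SDs are calibrated loosely to the descriptive
  statistics of a referral cohort recruited at ages 2–3 (e.g. adult verbal
  IQ centered near 62 with SD ≈ 45); optional `range_clip` bounds enforce
  instrument ranges but are **off by default**, because clipping distorts
  the variance decomposition that recovery tests rely on.
* **Outcomes.** Continuous: \(y = \alpha + \beta'z + \varepsilon\);
  ordinal: a unit-residual-variance latent \(\beta'z + \varepsilon\) cut
  at fixed thresholds (3, 4 and 7 levels by default, mirroring the
  independent-living 1–3, friendships 0–3 and work 1–7 scales). Residuals
  across all 14 outcomes are multivariate normal with an exchangeable
  correlation of 0.2 by default — the original analysis reports only that
  cross-outcome residual correlations were weak, so 0.2 is a simulation
  choice, not an empirical value.
* **Missingness.** Item-level cells are blanked independently (default 3%
  of predictor cells); whole-wave dropout follows a monotone discrete-time
  logistic hazard on race and maternal education (missing at random:
  dropout is higher for non-Caucasian participants and lower maternal
  education, matching the loss-to-follow-up pattern such cohorts report);
  adult outcomes are additionally missing completely at random (default
  10%). The true values of all blanked cells are retained for imputation
  accuracy tests.
* **Default conditions.** 123 participants — the sample size the package's
  sample-size machinery (`riley_min_r2`) is benchmarked at — and outcome
  loadings calibrated so that corrected performance reproduces the
  qualitative pattern the field reports: IQ and daily-living skills highly
  predictable from age 9 (population \(R^2\) ≈ 0.87/0.84/0.74), symptom
  severity and behavior modest and adolescent-driven (≈ 0.3–0.43),
  well-being/affect/depression at or near zero.

**What the generator does not emulate** — and hence what passing tests do
and do not show about real data: real instrument distributions are skewed,
bounded and integer-valued where the generator draws Gaussians; real
dropout can be missing-not-at-random; real predictor–outcome relationships
need not be linear; and the real cross-outcome residual correlation
structure is unknown beyond "weak". Recovery tests therefore demonstrate
that the *procedures are correct under their own assumptions*, not that
the assumptions hold in any particular cohort.

## 7. Sample-size planning and reliability ceilings

`riley_min_r2(n, p, S)` returns the minimum developable \(R^2\) under the
shrinkage-factor criterion — the closed form
\(R^2 = S\,(1 - e^{-p/(n(1-S))})\) of the equation
\(n = p/((S-1)\ln(1-R^2/S))\) at target shrinkage \(S = 0.9\) — monotone
decreasing in \(n\), increasing in \(p\), and cross-checked against a
bisection oracle to `1e-8`. Several variants of this family of criteria
exist and published minima cannot always be pinned to one of them; the
package implements the shrinkage-factor variant and records that identity
rather than claiming to reproduce any particular printed value.
`icc_ceiling()` renders the upper bound outcome unreliability places on
predictive \(R^2\) as \(\mathrm{ICC}^2\) (attenuation at both measurement
occasions); report figures draw these as dashed reference lines at ICC
0.95, 0.8, 0.7.

## 8. Numerical choices and degenerate inputs

* Coordinate descent: tolerance `1e-7` on coefficient changes; constant
  columns are inert (zero coefficient) rather than an error; warm starts
  along the decreasing penalty grid.
* Ordinal MLE: gradient max-norm `1e-6`; likelihood probabilities floored
  at `1e-300`; rank-deficient or separated fits are flagged with the
  suspect coefficients rather than masked.
* OLS on rank-deficient designs returns the minimum-norm (pseudoinverse)
  solution with a warning and a flag.
* LOOCV ties on the penalty grid break toward the larger penalty; KNN
  distance ties break by row order; mode ties break toward the lowest
  value — every tie-break is deterministic, which is what makes the full
  pipeline byte-identical across reruns at a fixed seed.
* Zero-variance outcomes, all-identical ordinal outcomes, empty penalty
  grids, all-missing columns, non-PSD residual correlation inputs, and
  priority points violating the 100-point budget all raise explicit
  errors naming the offending quantity.

## 9. Problem sizes used in the test and acceptance suites

Simulation-based checks use the smallest sizes at which the property under
test is statistically decisive: n = 10,000–20,000 for generator marginal
and correlation recovery (tolerances ±0.02–0.03), n = 5,000 for
latent-correlation and proportional-odds parameter recovery, n = 120–150
with 20–50 seeds for the optimism-correction studies (matching the target
cohort's scale), and 20 seeds × 2,000 draws for interval coverage. These
are the package's own choices balancing decisiveness against a test suite
that runs in minutes.

## 10. Limitations

The pipeline models each timepoint's snapshot rather than full repeated-
measures trajectories; a child assessed more intensively would need a
longitudinal model. Single imputation before splitting slightly flatters
validation performance. The facet-to-outcome mapping and elicited
priorities are illustrative, not population estimates. And internal
validation — however carefully optimism-corrected — is not external
validation: performance in a new cohort, with different recruitment,
instruments and era, is the only ultimate test.
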