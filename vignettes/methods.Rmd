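---
title: "Methods: screening, importance, selection, and equity decomposition for binary service utilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, importance, selection, and equity decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`healthequity` analyses utilization of a binary health service in coded
survey microdata through five stages. This vignette documents the models,
the parameters that matter, the numerical conventions, and the design
choices made where the design was genuinely open.

## The data model

A respondent record carries 14 categorical covariates (each with a fixed
integer code set), a raw household income, a province label, and a 0/1
outcome. Two variables are derived rather than observed:

* **Within-province income quintiles.** A respondent's percentile is the
  share of respondents in the same province with income less than or equal
  to theirs; the five bands are `[0, 20)`, `[20, 40)`, `[40, 60)`,
  `[60, 80)`, `[80, 100]`. Because the percentile uses "less than or
  equal", tied incomes always share a band, and a value sitting exactly on
  a boundary falls in the upper band (the respondent at the 20th
  percentile is "20th–39th"). Under this convention all-equal incomes in a
  province collapse into the top band — a deterministic, if arbitrary,
  resolution of a fully degenerate case. Quintile assignment depends on
  income only through within-province ranks, so it is invariant to
  monotone transforms of income.
* **Dummy encoding.** Factors are expanded into one 0/1 indicator per
  non-reference level, factors in reporting order and levels in ascending
  code order, with the lowest code as the default reference (matching the
  "(reference group)" rows of the standard regression-table layout). The
  seven-factor effect model has 17 non-intercept columns.

Cleaning drops rows with any missing required field, then rows with
non-positive income, then rows above a configurable upper income quantile
(default 0.999, a light outlier screen). The original study reports only
the before/after sample sizes of its cleaning, not the rules, so the rule
set here is configurable and no attempt is made to replicate the published
respondent count.

## Synthetic microdata

The generator exists so that every downstream stage can be tested against
known truth, the real survey file being access-restricted. Defaults are
fixed once, from the published study's descriptive tables:

* Covariates are drawn independently from the published marginal category
  frequencies (stored as counts and normalized, which also resolves two
  small internal inconsistencies in the printed percentages).
* Household income is log-normal, `meanlog = log(60000)` (a realistic
  annual household income in CNY for this population), `sdlog = 0.6`, with
  province effects `N(0, 0.2)` on `meanlog` across 31 provinces.
* The outcome is Bernoulli with
  `logit p = β₀ + Σ βⱼ xⱼ + g·r`, where the `βⱼ` default to the published
  logistic coefficients, `r` is the within-province fractional income rank
  and `g` an optional direct income gradient. The error term of the logit
  formulation is realized implicitly through Bernoulli sampling (the
  standard latent-logit equivalence), not as an additive draw. `β₀`
  defaults to `logit(0.8189) − Σ βⱼ E[xⱼ]`, which centres the expected
  linear predictor on the published utilization rate; by Jensen's
  inequality the realized rate sits slightly below the target (about 79.6%
  at the default coefficients), which no test depends on.
* **Income–covariate dependence hook.** With independent covariates every
  determinant's own concentration index is ≈ 0 and the decomposition is
  vacuous. Setting `income_by_education = 0.15` shifts `meanlog` by 0.15
  per education level above the middle, inducing the income–education
  association that makes factor concentration indices non-zero. The
  default end-to-end configuration (`default_pipeline_config()`) enables
  the hook (and a direct gradient of 0.3); the plain
  `generator_config()` default keeps covariates independent, which is the
  right null for calibration tests.

What the generator does **not** emulate: the survey's multistage
probability-proportional-to-size sampling design and clustering, survey
weights, item-level missingness mechanisms, and realistic correlation
among the categorical covariates beyond the single income–education hook.
Passing tests therefore demonstrate correctness of the estimators under a
clean generative model, not robustness to the design effects of the real
survey.

## Univariate screening

Each factor is cross-tabulated against the outcome and tested with the
Pearson χ² statistic `Σ (O − E)²/E`, `(L − 1)` degrees of freedom, **no
continuity correction** — the convention that reproduces the published
2×2 statistics exactly. Factors with `p ≥ α` (default `α = 0.05`,
configurable; the source text says only "statistically significant") are
excluded from all downstream stages.

The published screening table ships as a fixture
(`table3_counts()`). Six of its fourteen panels are flagged and excluded
from exact assertions: three have margins inconsistent with the
descriptive table, two print their statistic only in scientific shorthand,
and one (`sick`) is internally consistent yet its printed statistic
(399.049) disagrees with direct computation (≈ 339.05); the package
asserts nothing about flagged panels beyond their flags. One further
caveat belongs here: the asymptotic χ² p-value is a poor reference when
expected counts fall below 5, so the oracle tests compare p-values against
an exact permutation null only on tables satisfying the classical validity
rule, and compare statistics (which are exact regardless) on sparse ones.

## Out-of-bag permutation importance

The ensemble is bagging of CART trees: each of `n_estimators` trees is
fitted (via **rpart**, `cp = 0`) on a bootstrap resample, and the rows a
tree never saw form its out-of-bag (OOB) set. For feature `X` the score is

```
OOB_store(X) = Σᵢ (err_OOB2ᵢ − err_OOB1ᵢ) / N
```

with `err_OOB1ᵢ` tree *i*'s OOB error and `err_OOB2ᵢ` the same error after
randomly permuting `X`'s values over that tree's OOB rows — one
permutation per tree per feature, OOB rows only. Both per-tree error
vectors are kept in the result, so the aggregate can be (and is) re-derived
by a literal loop in the tests. Trees with an empty OOB set are skipped
with `N` decremented.

Conventions and knobs:

* **Two modes.** `regression` (default) fits regression trees on the 0/1
  outcome and scores squared error — the %IncMSE-style trace the original
  analysis printed; `classification` uses majority vote and
  misclassification rate. Hyperparameter search uses classification
  accuracy, matching the search the study describes. Both are exposed
  because the source mixes the two traditions.
* **mtry.** Per-split feature subsampling is not expressible with rpart as
  the base learner, so `mtry` is implemented as a per-tree random subspace
  draw. The default is all features (pure bagging): with per-tree
  subsampling, √p would leave most trees blind to the strong features and
  degrade the importance contract; users wanting a random-subspace
  ensemble can set `mtry` explicitly.
* **Coding.** Importance runs on integer-coded factors by default (one
  column per factor, so the ranking is per factor); a one-hot design can
  be passed instead. Which coding the original analysis used is not
  stated.
* **Search.** `random_search_forest()` draws configurations uniformly over
  the documented ranges (trees 1–500, depth 1–20, min-split 2–20, min-leaf
  1–10) and scores them by stratified 5-fold CV accuracy, returning the
  best configuration and the full trial log. The search *machinery* is the
  tested artifact; a specific argmax is data- and seed-dependent (the
  source itself prints two different optima) and is not a target. The
  pipeline leaves the search off by default (`search_iter = 0`) and, when
  enabled, runs it on a 4,000-row stratified subsample — the
  hyperparameter surface of bagged trees is flat enough that a subsample
  locates a competitive region at a fraction of the cost.

## L1-penalized selection

`fit_lasso_path()` solves the penalized binomial likelihood over a
descending log-spaced λ grid (intercept unpenalized, predictors
standardized internally, coefficients reported on the original scale),
via **glmnet**. `cv_select()` uses stratified k-fold CV (default k = 10)
with binomial deviance loss (the source's "mean square error" would be
either deviance or MSE in glmnet terms; both are selectable) and returns
`λ_min` and `λ_1se`. A factor is *selected* iff any of its dummy columns
is nonzero at the chosen λ.

λ roles: `λ_min` (the study's stated pick, and the default passed
downstream) minimizes predictive loss and by construction tends to retain
some null columns; `λ_1se` is the parsimonious choice that excludes them.
The truth-recovery tests assert containment of the true support at
`λ_min` and exact support recovery at `λ_1se` — asking `λ_min` to exclude
nulls would contradict how cross-validated lasso behaves. The published
`λ_min = 0.000677` is a data-dependent quantity of the restricted
microdata and is documented as non-reproducible; selection behaviour is
validated on synthetic truth instead. The source's "100 iterations" is
read as a solver iteration cap (`maxit`), the only interpretation glmnet
exposes directly.

## Logistic model and marginal effects

`fit_logit()` is maximum likelihood via IRLS (convergence tolerance 1e-10
on the relative deviance change, up to 100 iterations) with Wald standard
errors; collinear columns are detected by QR rank and raised as errors
naming the columns, and (quasi-)complete separation — fitted probabilities
numerically 0/1 alongside diverging coefficients — raises an explicit
separation error. Odds ratios are `exp(β)` with symmetric-in-log 95%
intervals `exp(β ± 1.96·se)`; p-values are Wald (the source does not say
Wald or LR; Wald matches its symmetric intervals). Since every regressor
in the effect model is a dummy, average marginal effects use the discrete
change `mean[p̂(xⱼ=1) − p̂(xⱼ=0)]` rather than the density derivative;
non-indicator columns fall back to `mean[p̂(1−p̂)]·βⱼ`.

## Concentration index and Wagstaff decomposition

* **Fractional ranks.** After a stable sort by income, respondent *i*'s
  rank is (cumulative weight of the strictly poorer + half own
  weight)/total weight; tied incomes share their block's weighted mean
  rank. The weighted mean rank is exactly 0.5 by construction. Ranks
  default to raw household income over the whole sample; which income
  concept (household total vs per capita) feeds the ranks vs the quintile
  covariate is not stated in the source, so both are configurable and
  household total is the default for both.
* **Index.** `CI = 2 cov(y, r)/μ` with the *population* covariance
  (divide by total weight, not n−1) — the convenient-covariance form of
  the health-economics literature; the difference is O(1/n). For a binary
  outcome the plain index is bounded by `|CI| ≤ 1 − μ`; no
  Erreygers/Wagstaff normalization is applied by default because the
  source reports the plain index. The concentration curve accumulates
  outcome share against population share in rank order; twice the signed
  area between curve and diagonal equals the index up to O(1/n)
  discreteness, which the tests verify at 1e-3 for n = 10,000.
* **Decomposition.** For each non-reference dummy *j*:
  elasticity `= AMEⱼ·x̄ⱼ/μ` (the AME standing in for the linear
  coefficient, as the source prescribes for a nonlinear model), factor
  index `Cⱼ = 2 cov(xⱼ, r)/x̄ⱼ` over the *same* ranks (required for the
  identity), contribution `= elasticity × Cⱼ`, rate
  `= contribution/C × 100`. The residual `GC_ε/μ` is defined as
  `C − Σ contributions`, so the identity holds to machine precision by
  construction *and* is asserted on every run — the meaningful check is
  that contributions, not the residual, carry the index when the
  generating model says they should. Zero-mean columns get contribution 0
  and a flag. The published decomposition's elasticity column cannot be
  reproduced from the published coefficients and means under any standard
  formula (e.g. 2.735 for high-school education); only its internal
  arithmetic (elasticity × CI = contribution, contribution/C = rate) is
  asserted, and the provenance of those printed elasticities remains an
  open question.

## Pipeline and problem sizes

`run_pipeline()` wires the stages in study order — screen, rank, select,
fit, decompose — with one master seed from which every stage derives its
own (so runs are byte-reproducible), per-stage timing, partial-output
persistence on failure, and a JSON report validated against a shipped
schema. The χ² screen gates everything downstream; the LASSO sees all
screened factors' dummies (not only the top-ranked ones), mirroring the
study's flow where the forest ranks but does not prune.

Default validation sizes, chosen to make the statistical contracts sharp
while keeping a full run in seconds on one CPU: end-to-end runs and
calibration checks at n = 20,000; truth-recovery suites over 20 seeds
(logit recovery at n = 20,000, lasso support at n = 5,000, forest ranking
at n = 600 with 50 trees); oracle equivalences at n in the hundreds. At
n = 20,000 the weakest published effects (gender, β = 0.083) often fail
the univariate screen — a power consequence of the scaled-down sample, so
end-to-end tests assert identity, sign and attribution properties rather
than a fixed selected-factor count.

## Known limitations

* No survey weights, design effects, or clustering; all counts are
  unweighted, as in the source analysis.
* No inference (standard errors, dominance tests) for the concentration
  index; none is reported in the source.
* The bagged ensemble subsamples features per tree, not per split; it is
  bagging with an optional random-subspace draw, not a per-split random
  forest.
* Published fitted values that require the restricted microdata — the
  headline index 0.0121, the fitted coefficient table, the printed
  elasticities, the optimal hyperparameters and `λ_min` — are regeneration
  targets in shape only; the package validates the estimators on synthetic
  truth.
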