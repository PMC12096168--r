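# healthequity

Who gets a basic public-health service, and is access tilted toward the
rich? `healthequity` is an R package for answering both questions in
categorical survey microdata on migrant ("mobile") populations, where the
service of interest — here, receipt of community health education — is a
binary outcome and the candidate determinants are coded survey items
(income rank, age band, education, household-registration status, mobility
range and reason, health records, …).

It implements, as one tested pipeline:

1. **Univariate screening** — level × outcome contingency tables and
   Pearson χ² tests of independence (no continuity correction);
2. **Importance ranking** — a bagged CART ensemble with the out-of-bag
   permutation score
   `OOB_store(X) = Σᵢ (err_OOB2ᵢ − err_OOB1ᵢ) / N`,
   where `err_OOB1ᵢ` is tree *i*'s error on its out-of-bag rows and
   `err_OOB2ᵢ` the same error after randomly permuting feature *X* on those
   rows, plus randomized hyperparameter search with stratified 5-fold CV;
3. **Variable selection** — L1-penalized logistic regression over a λ path
   with stratified 10-fold cross-validation (`λ_min`, `λ_1se`);
4. **Effect estimation** — binary logistic regression
   `logit P(yᵢ = 1) = β₀ + Σⱼ βⱼ xᵢⱼ`, reported as odds ratios with Wald
   95% CIs, and discrete-change average marginal effects (AMEs);
5. **Equity analysis** — fractional income ranks `Rᵢ`, the concentration
   index `CI = 2 cov(yᵢ, Rᵢ)/μ` with its concentration curve, and the
   Wagstaff decomposition
   `C = Σⱼ (AMEⱼ · x̄ⱼ / μ) · Cⱼ + GC_ε/μ`,
   attributing pro-rich inequality (`CI > 0`) to individual determinants.

Because the real survey microdata (the China Migrants Dynamic Survey) are
access-restricted, the package ships a **synthetic microdata generator**
(`simulate_survey()`) that emulates the survey's structure — 14 coded
covariates with realistic marginals, province-level log-normal household
income, within-province income quintiles, and an outcome drawn from a
logistic model whose coefficients default to the published estimates — so
every stage can be validated against known ground truth.

## Worked example

```r
library(healthequity)

bundle <- run_pipeline(default_pipeline_config(n = 20000, seed = 1))
print(bundle)
#> <report_bundle>
#>   n = 19980, outcome rate = 0.7957
#>   screened-in factors: age_group, education, mobility_range,
#>     income_quintile, health_record
#>   importance ranking: health_record > education > age_group >
#>     income_quintile > mobility_range
#>   selected factors: age_group, education, mobility_range,
#>     income_quintile, health_record
#>   concentration index: 0.020006 (pro-rich)
```

About 80% of the simulated respondents receive health education; factors
whose χ² screen fails at α = 0.05 (at n = 20,000 the weakest true effects,
such as gender's β = 0.083, usually lack power) are dropped before the
forest; the OOB permutation score ranks the strong determinants first; the
LASSO keeps them; and the concentration index is positive — utilization is
concentrated among richer respondents, as expected since the generating
model gives higher income ranks higher odds. The decomposition table
(`bundle$equity$decomposition`) attributes the index to the determinants,
and the identity `C = Σ contributions + residual` closes to machine
precision on every run.

Individual stages are plain functions: `crosstab()` / `chi2_test()`,
`fit_forest()` / `oob_importance()` / `random_search_forest()`,
`fit_lasso_path()` / `cv_select()` / `selected_factors()`, `fit_logit()` /
`odds_ratio_table()` / `average_marginal_effects()`, `fractional_rank()` /
`concentration_index()` / `wagstaff_decompose()`. A thin command-line
wrapper with `simulate` / `univariate` / `importance` / `select` / `fit` /
`equity` / `run-all` subcommands is installed at
`inst/cli/healthequity.R`.

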