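# twasbias

Monte-Carlo simulation of **selection bias in integrated transcriptome
association analysis**, and of inverse probability weighting (IPW) as a
corrective measure.

## The problem

Two-stage least squares (2SLS) is a standard way to estimate the association
between genetically regulated gene expression and a trait by combining two
independent datasets:

1. **Stage 1 (TWAS data, size n₁):** regress measured expression on
   genotype, `x_i = α₀ + z_i1 α₁ + z_i2 α₂ + δ_i`, and keep the estimates
   `α̂`.
2. **Stage 2 (GWAS data, size n₂):** form predicted expression
   `x̂_j = α̂₀ + z_j1 α̂₁ + z_j2 α̂₂` and regress the trait on it,
   `y_j = γ₀ + x̂_j γ₁ + ε_j`. The slope `γ̂₁` estimates the
   expression–trait association.

The approach presumes both datasets are random samples from the same target
population. Real expression panels and trait cohorts usually are not —
post-mortem convenience samples, disease-enriched cohorts, healthy-volunteer
studies — and when the sampling mechanism is related to the trait, `γ̂₁`
becomes biased and its confidence intervals misleading.

`twasbias` builds a full in-silico laboratory for this question around body
mass index (BMI) as the trait: a generative population model of genotype,
single-gene expression (log2 scale) and natural-log BMI; cohort-mimicking
biased sampling that matches a reference cohort's BMI **decile profile**
(individual selection probabilities `p_i ∝ w_i`, the fraction of the
reference cohort in individual *i*'s population BMI decile); and IPW in the
stage-1 fit with known weights `1/p_i` or with weights estimated from a BMI
prediction model (age + weight) fitted in a survey-like referent. Four
published cohort BMI category tables (NHANES, GTEx, CRIC, GENE, by sex) ship
as plain-text fixtures and drive synthetic reference cohorts.

Per scenario the package reports the Monte-Carlo mean estimate, relative
bias `100(γ̂₁ − γ₁)/γ₁`, mean 95% CI length, and coverage of the true
`γ₁ = 0.15`.

## Worked example

Biased TWAS sampling mimicking the expression-panel cohort, random GWAS
sampling (200 replicates on one fixed population of 100,000 for speed):

```r
library(twasbias)

cohort_spec("GTEx", "women")
#> <cohort_spec> GTEx / women (n = 116)
#>   BMI category proportions: <18.5: 0.000, 18.5-24.9: 0.353, 25.0-29.9: 0.440, >=30.0: 0.207

cfg <- scenario_config("GTEx-RS", replicates = 200, base_seed = 42,
                       regenerate_population = FALSE)
res <- run_scenario(cfg)
res
#> <scenario_result> GTEx-RS | IPW: none | 200 replicates
#>   mean gamma1_hat = 0.218, mean relative bias = 45.2%, mean CI length = 0.252, coverage = 0.715

stage_one_bias_table(res)
#> # A tibble: 3 × 5
#>   coefficient   mean median iqr_lo iqr_hi
#>   <chr>        <dbl>  <dbl>  <dbl>  <dbl>
#> 1 alpha0       -5.00  -5.11  -5.91  -4.08
#> 2 alpha1      -33.0  -31.9  -63.6   -4.76
#> 3 alpha2      -19.7  -23.0  -51.9   17.5
```

Read: sampling the TWAS side like a lean convenience cohort biases every
stage-1 coefficient downward (intercept −5%, SNP effects −33%/−20% on
average), which compresses predicted expression and inflates the stage-2
association estimate by ~45% on average, with coverage of the nominal 95%
interval at 71.5% instead of the ~75% seen under random sampling (itself
below 95% because predicted expression is a single mean imputation).

`tidy(res)` returns the 200 per-replicate rows; `glance(res)` the one-row
summary; `autoplot(res)`, `plot_relative_bias()`,
`plot_predicted_expression()` and `plot_stage1_bias()` draw the standard
figures. `scenario_config("GTEx-RS", ipw = "known")` (or `"estimated"`)
switches on inverse probability weighting in stage 1;
`compare_cohorts_to_referent()` reproduces the cohort-vs-survey KS and
Wilcoxon comparisons on the synthetic cohorts.

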