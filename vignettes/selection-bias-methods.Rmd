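---
title: "Selection bias in two-stage transcriptome association analysis: model, sampling schemes, and weighting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection bias in two-stage transcriptome association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twasbias)
library(ggplot2)
```

## The question

Integrative transcriptome analyses routinely combine an expression panel
(a TWAS-style dataset pairing genotypes with measured gene expression) with
an independent trait dataset (a GWAS-style dataset pairing genotypes with a
phenotype). The standard two-stage least-squares pipeline fits
genotype→expression in the first dataset, predicts expression in the second
from genotype alone, and regresses the trait on that prediction. Both
datasets are treated as if they were random samples from one target
population — but in practice they rarely are: expression panels are often
convenience samples (e.g. post-mortem donors), and trait cohorts may be
disease-enriched or unusually healthy.

`twasbias` is a Monte-Carlo laboratory for this problem. It simulates a
well-defined target population, draws the two datasets either at random or
through cohort-mimicking biased sampling keyed to body-mass index (BMI), and
measures what happens to the two-stage estimate of the expression–trait
association: its bias, its confidence-interval length, and the coverage of
nominal 95% intervals. Inverse probability weighting (IPW) with known and
with estimated selection probabilities is provided as a corrective measure.

## The generative model

For individual $i$ in a population of size $N$:

$$x_i = \alpha_0 + z_{i1}\alpha_1 + z_{i2}\alpha_2 + \delta_i,
\qquad \delta_i \sim N(0, \sigma_\delta^2),$$

$$y_i = \gamma_0 + x_i \gamma_1 + \epsilon_i,
\qquad \epsilon_i \sim N(0, \sigma_\epsilon^2),$$

with $z_{i1}, z_{i2} \sim \mathrm{Binomial}(2, \mathrm{maf})$ two independent
biallelic SNPs in Hardy–Weinberg equilibrium, $\delta \perp \epsilon$, and
both independent of the genotypes. Here $x$ is single-gene expression on a
log2-normalized scale and $y$ is natural-log BMI, so $\mathrm{BMI} = e^y$.

Defaults (`dgp_params()`):

| parameter | default | units / meaning |
|---|---|---|
| `maf` | 0.20 | minor allele frequency, both SNPs |
| `alpha1`, `alpha2` | 0.2 | log2 expression units per minor allele |
| `alpha0` | 10.23 | log2 units; equals `mu1 - 2*maf*(alpha1+alpha2)` |
| `mu1` | 10.39 | target mean expression (log2 units) |
| `sigma_delta` | 1.6 | expression residual sd (log2 units) |
| `gamma1` | 0.15 | log BMI per log2 expression unit — the estimand |
| `sigma_eps` | 0.065 | trait residual sd (log BMI units) |
| `mu2` | 3.36 | target mean log BMI ($e^{3.36} \approx 28.8$ kg/m²) |
| `pop_size` | 100000 | population size $N$ |

Two coupled calibration identities organise these choices. First, the
intercept satisfies $\alpha_0 = \mu_1 - 2\,\mathrm{maf}\,(\alpha_1+\alpha_2)$,
so mean expression hits the target $\mu_1$; with the default effects of 0.2
this gives exactly 10.23, and `dgp_params(alpha0 = "formula")` recomputes the
identity if you change the effects or the MAF. Second, the trait intercept is
*derived per population* as $\gamma_0 = \mu_2 - \bar{x}\gamma_1$ using the
realized mean expression $\bar{x}$ (`derive_gamma0()`), pinning mean log BMI
at $\mu_2$ regardless of the realized expression draw. The per-allele effect
of 0.2 (rather than a smaller value) is what makes the genotype a usable,
if still weak, instrument at the default TWAS size: the per-SNP standard
error of a stage-1 coefficient at $n_1 = 750$ is
$\sigma_\delta/\sqrt{n_1 \cdot 2\,\mathrm{maf}(1-\mathrm{maf})} \approx 0.10$,
half the effect size. The two-stage estimator's behaviour in this
weak-instrument regime — noticeable small-sample attenuation and coverage
well below nominal even under random sampling — is itself one of the
phenomena the simulation is designed to exhibit.

Because $\sigma_\epsilon$ is small relative to $\gamma_1 \sigma_\delta$,
log BMI is nearly a deterministic function of expression; selecting
individuals by BMI is therefore almost selecting them by expression, which
is what makes BMI-keyed sampling bite on the stage-1 fit.

```{r population}
pop <- simulate_population(dgp_params(pop_size = 20000L), seed = 1)
population_summary(pop)
```

## Synthetic reference cohorts

The biased sampling schemes are keyed to four reference cohorts — a
population-representative survey (NHANES), a post-mortem expression panel
(GTEx), a chronic-kidney-disease cohort (CRIC), and a young healthy
volunteer cohort (GENE) — for which only *four-category* BMI summaries
(underweight / normal / overweight / obese, by sex, with sample sizes) are
publicly available. `builtin_cohort_table()` carries those eight rows;
`sample_reference_bmi()` draws synthetic cohort samples whose category
frequencies match them.

The shape of BMI *inside* each category is not identified by a 4-bin
summary, so it is a modelling choice (`default_within_category_model()`):
uniform within each bounded category and $30 + \mathrm{Exp}(\text{mean }5)$
above 30, capturing the right skew of obesity. Two consequences matter for
interpretation:

* Everything the generator knows about a cohort is its category profile.
  Cohorts that differ from the referent mainly *within* categories (as the
  real expression-panel cohort does, being tighter and leaner than the
  survey inside the same bins) are reproduced only at category resolution,
  so distributional tests separate synthetic GTEx from synthetic NHANES far
  less often than the real microdata would.
* The decile weights, and hence the *magnitudes* of the biased-scenario
  results, depend on these shapes. The package's biased-scenario claims are
  therefore directional (sign of bias, degradation of coverage), not
  numerical reproductions; only the random-sampling scenario has
  fully-determined published values to match.

Covariates are attached by `attach_covariates()`: height truncated-normal
(mean 1.65 m, sd 0.08 m, on [1.40, 2.05]), independent of BMI; weight
defined exactly as $\mathrm{BMI} \times \mathrm{height}^2$; age uniform on
[21, 70]. This makes BMI predictable from (age, weight) with $R^2 \approx
0.85$ — good but imperfect, which is precisely the knob that gives
*estimated* inverse-probability weights realistic error. The height sd is
the tuning parameter: smaller values push $R^2$ toward 1 and estimated
weights toward known weights.

## Sampling schemes and weights

Random sampling (`random_sample_split()`) draws $n_1 + n_2$ distinct
individuals without replacement and splits them into a TWAS set of
$n_1 = 750$ and a GWAS set of $n_2 = 1500$.

Biased sampling mimics a reference cohort through decile matching:

1. `population_deciles()` — the nine BMI decile cut points of the simulated
   population (type-7 empirical quantiles; bins left-closed, right-open).
2. `decile_weights()` — $w_k$, the fraction of the reference cohort's BMI
   values in population decile $k$.
3. `selection_probabilities()` — every individual inherits its decile's
   $w_k$; the vector is normalized to sum to 1 *over the population* (the
   only non-circular reading: normalizing over the drawn sample would
   require the sample first).
4. `draw_biased_sample()` — with-replacement draws with those probabilities,
   recording each drawn individual's probability.

Individuals in zero-weight deciles are simply never drawn. For IPW:

* `ipw_known()` returns $1/p_i$ for the drawn individuals — the weights one
  could use if the selection mechanism were known exactly.
* `ipw_estimated()` mimics the realistic case: an ordinary least-squares
  model of BMI on age and weight is fitted to a synthetic survey referent
  (`fit_bmi_predictor()`), BMI is predicted for each sampled individual,
  mapped to a population decile, and that decile's probability is inverted.
  A predicted decile can have zero weight through prediction error; such
  individuals receive the largest finite weight in the sample (configurable
  cap) — preserving ordering without infinities. Because weighted least
  squares is scale-invariant, the normalization of estimated probabilities
  is immaterial to the fit; supplying the population normalizer merely makes
  the weights numerically comparable to `ipw_known()`.

IPW applies to the stage-1 fit only; stage 2 is always unweighted.

## The two-stage pipeline and its metrics

`stage_one()` fits $x \sim z_1 + z_2$ by (optionally weighted) least
squares; `predict_expression()` forms $\hat{x}_j = \hat\alpha_0 +
z_{j1}\hat\alpha_1 + z_{j2}\hat\alpha_2$ with no residual noise (single mean
imputation); `stage_two()` regresses $y$ on $\hat{x}$ and reports a t-based
95% interval with $n_2 - 2$ degrees of freedom and classical homoskedastic
standard errors — the default behaviour of standard linear-model software,
and deliberately *not* corrected for the measurement error in $\hat{x}$.
The resulting under-coverage below 95% even under random sampling is a
finding the pipeline is meant to exhibit, not a defect to repair.

Per replicate the package records relative bias
$100(\hat\gamma_1 - \gamma_1)/\gamma_1$, the CI length, and a closed-interval
coverage indicator; `summarize_scenario()` aggregates means, medians,
type-7 interquartile ranges, and coverage across replicates.

```{r scenario}
cfg <- scenario_config("GTEx-GENE", replicates = 50, base_seed = 9,
                       params = dgp_params(pop_size = 20000L),
                       regenerate_population = FALSE)
res <- run_scenario(cfg)
glance(res)[, c("scenario", "mean_estimate", "mean_rel_bias", "coverage")]
```

```{r plot, fig.width = 6, fig.height = 3.5}
autoplot(res)
```

## Scenario orchestration and reproducibility

`scenario_config()` encodes the four study scenarios — RS (both sides
random), GTEx-RS (biased TWAS only), GTEx-CRIC and GTEx-GENE (both sides
biased) — with IPW variants for the biased-TWAS case. Design choices where
the procedure was genuinely open:

* **Population per replicate.** By default a fresh $N = 100{,}000$
  population is generated for every replicate, making replicates fully
  independent; `regenerate_population = FALSE` generates one population from
  the base seed and resamples it, which is an order of magnitude faster and
  conditions all replicates on one realized population (its stage-1
  coefficients then center on that population's realized values, which
  deviate from the generative ones by $O(N^{-1/2})$, about ±4.5% relative at
  the defaults).
* **Cohorts per replicate.** Reference-cohort samples are regenerated each
  replicate at the published cohort sizes (GTEx women $n = 116$, etc.), so
  small-cohort noise in the decile weights propagates into the results;
  `fixed_cohorts = TRUE` freezes them.
* **Seeding.** `base_seed` spawns one seed per replicate (plus one for the
  fixed population and one for fixed cohorts) by a single `sample.int()`
  draw; each replicate then consumes its stream in a fixed order —
  population (if regenerated), TWAS reference, GWAS reference, TWAS draw,
  GWAS draw, then the IPW referent. Drawing the IPW referent *after* the
  sample draws means configurations differing only in the `ipw` setting see
  identical samples under a shared base seed, so IPW comparisons are paired.
  Identical configuration and seed give byte-identical results.

## What the tests establish, and problem sizes

The test suite checks the pipeline at three levels. Exact oracles: weighted
least squares against replicated-row least squares and against `lm`;
closed-form two-point fits; the relative-bias and coverage formulas.
Distributional oracles at reduced scale (populations of 20,000–50,000,
hundreds of replicates): recovery of all generative coefficients, residual
independence, nominal coverage when the true expression is used as the
stage-2 regressor, and equivalence of uniform-weight biased sampling to
random sampling. Full-scale acceptance runs (2000 replicates; random
sampling with per-replicate regeneration at $N = 100{,}000$, biased
scenarios on one fixed population) check the random-sampling summary against
its published values and the biased scenarios for their directional
properties. These sizes are the package's chosen desk-scale study
conditions; all are reproducible from fixed seeds.

## Known limitations

* Biased-scenario *magnitudes* are not comparable to published values
  obtained with real cohort microdata; only directions and qualitative
  contrasts are. In particular, with the milder synthetic selection the
  coverage ordering among biased scenarios and the coverage benefit of IPW
  need not match results driven by stronger selection: IPW removes stage-1
  bias but inflates stage-1 variance, which the stage-2 intervals ignore,
  so when the bias being removed is small IPW can *lower* coverage.
* The model is single-gene, two-SNP, linear, with independent SNPs; there is
  no LD, no multi-gene regularized prediction, and no summary-statistic
  mode.
* Expression on the anti-log scale is reported as $2^{\text{mean}(x)}$, a
  geometric-mean convention flagged in `population_summary()` and
  `mean_predicted_expression()`; it is not the arithmetic mean of abundance
  and should not be compared across conventions.
* IPW is plain inverse weighting with a single fallback cap; no
  stabilization, truncation, calibration, or doubly-robust estimation.
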