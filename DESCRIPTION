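Package: twasbias
Title: Selection Bias and Inverse Probability Weighting in Integrated
    Transcriptome Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Monte-Carlo simulation toolkit for studying how non-random
    (cohort-mimicking) sampling of the expression (TWAS) and trait (GWAS)
    datasets biases two-stage least-squares estimates of the association
    between genetically predicted gene expression and a quantitative trait.
    Provides a population-level generative model of genotype, expression and
    log body-mass index; decile-matched biased resampling driven by
    reference-cohort BMI category tables; inverse probability weighting with
    known and estimated selection probabilities; and scenario orchestration
    with Monte-Carlo summaries (mean estimate, relative bias,
    confidence-interval length and coverage).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
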