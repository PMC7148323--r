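#' Decile cut points of the population BMI distribution
#'
#' Nine empirical quantiles at probabilities 0.1, ..., 0.9 (type-7 linear
#' interpolation). Downstream decile bins are left-closed, right-open; the
#' bottom and top bins are unbounded below and above.
#'
#' @param bmi_pop Numeric vector of population BMI values with at least 10
#'   distinct values.
#' @return Numeric 9-vector of nondecreasing cut points.
#' @export
population_deciles <- function(bmi_pop) {
  if (length(unique(bmi_pop)) < 10) {
    stop("need at least 10 distinct BMI values to form deciles")
  }
  unname(stats::quantile(bmi_pop, probs = seq(0.1, 0.9, by = 0.1), type = 7))
}

# decile index in 1..10 for each value; values equal to a cut fall upward
decile_index <- function(bmi, decile_cuts) {
  findInterval(bmi, decile_cuts) + 1L
}

#' Reference-cohort fractions per population decile
#'
#' `w[k]` is the fraction of the reference cohort's BMI values that fall in
#' population decile `k`. A reference cohort concentrated in low BMI deciles
#' yields a weight vector with mass at the bottom, and hence biased sampling
#' toward lean individuals.
#'
#' @param reference_bmi Non-empty numeric vector of reference-cohort BMI.
#' @param decile_cuts Cut points from [population_deciles()].
#' @return Numeric 10-vector of fractions summing to 1.
#' @export
decile_weights <- function(reference_bmi, decile_cuts) {
  if (length(reference_bmi) == 0) stop("empty reference sample")
  idx <- decile_index(reference_bmi, decile_cuts)
  tabulate(idx, nbins = 10L) / length(reference_bmi)
}

#' Per-individual selection probabilities from decile weights
#'
#' Every individual receives its decile's reference fraction `w[k]`, and the
#' vector is normalized to sum to 1 over the population, so drawing with these
#' probabilities reproduces the reference cohort's decile profile in
#' expectation.
#'
#' @param pop_bmi Population BMI vector.
#' @param w Decile weight 10-vector from [decile_weights()].
#' @param decile_cuts Cut points from [population_deciles()].
#' @return Numeric vector of probabilities, one per individual, summing to 1.
#' @export
selection_probabilities <- function(pop_bmi, w, decile_cuts) {
  stopifnot(length(w) == 10L, all(w >= 0))
  if (sum(w) <= 0) stop("all-zero decile weights: no sampleable individuals")
  raw <- w[decile_index(pop_bmi, decile_cuts)]
  total <- sum(raw)
  if (total <= 0) stop("no population member falls in a positive-weight decile")
  raw / total
}

#' Draw a biased sample with replacement
#'
#' `size` independent draws from the population with per-individual
#' probabilities `p`, recording each drawn individual's probability for
#' inverse-probability weighting.
#'
#' @param p Selection probabilities over the population (summing to 1).
#' @param size Number of draws.
#' @param seed Optional integer seed (RNG-state preserving).
#' @param role `"TWAS"` or `"GWAS"`; metadata only.
#' @return A tibble with columns `index` (position into the population, with
#'   multiplicity) and `p_at_draw`, plus attributes `scheme = "weighted"` and
#'   `role`.
#' @export
draw_biased_sample <- function(p, size, seed = NULL, role = "TWAS") {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-6, size >= 1)
  draw <- function() sample.int(length(p), size, replace = TRUE, prob = p)
  idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- tibble::tibble(index = idx, p_at_draw = p[idx])
  attr(out, "scheme") <- "weighted"
  attr(out, "role") <- role
  out
}

#' Random split into TWAS and GWAS samples
#'
#' Samples `n1 + n2` distinct individuals uniformly without replacement and
#' partitions them at random into a TWAS set of size `n1` and a GWAS set of
#' size `n2`. This is the no-selection-bias sampling scheme.
#'
#' @param pop_size Population size (or a population tibble, whose row count is
#'   used).
#' @param n1,n2 TWAS and GWAS sample sizes.
#' @param seed Optional integer seed (RNG-state preserving).
#' @return A list with tibbles `twas` and `gwas`, each with column `index`,
#'   attribute `scheme = "random"`.
#' @export
random_sample_split <- function(pop_size, n1 = 750, n2 = 1500, seed = NULL) {
  if (is.data.frame(pop_size)) pop_size <- nrow(pop_size)
  if (n1 + n2 > pop_size) {
    stop("n1 + n2 = ", n1 + n2, " exceeds population size ", pop_size)
  }
  draw <- function() sample.int(pop_size, n1 + n2, replace = FALSE)
  idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  twas <- tibble::tibble(index = idx[seq_len(n1)])
  gwas <- tibble::tibble(index = idx[n1 + seq_len(n2)])
  attr(twas, "scheme") <- "random"; attr(twas, "role") <- "TWAS"
  attr(gwas, "scheme") <- "random"; attr(gwas, "role") <- "GWAS"
  list(twas = twas, gwas = gwas)
}

#' Known inverse-probability weights
#'
#' The reciprocal of each drawn individual's true selection probability, as
#' used in the sampling step.
#'
#' @param sample A tibble from [draw_biased_sample()] (needs `p_at_draw`).
#' @return Numeric vector of weights `1 / p_at_draw`.
#' @export
ipw_known <- function(sample) {
  p <- sample[["p_at_draw"]]
  if (is.null(p)) stop("sample carries no selection probabilities (random scheme?)")
  if (any(p <= 0)) stop("zero selection probability among drawn individuals")
  1 / p
}

#' Fit the BMI prediction model for estimated weights
#'
#' Ordinary least squares of BMI on age and weight in a reference sample
#' (the survey-like cohort standing in for the general population). The fitted
#' coefficients are used to predict BMI for sampled individuals whose true
#' selection probabilities are treated as unknown.
#'
#' @param referent A tibble with columns `bmi`, `age`, `weight` (e.g. from
#'   [sample_reference_bmi()]).
#' @return Named coefficient vector `(intercept, age, weight)`.
#' @export
fit_bmi_predictor <- function(referent) {
  stopifnot(all(c("bmi", "age", "weight") %in% names(referent)))
  if (nrow(referent) < 3) stop("need at least 3 records to fit the BMI predictor")
  X <- cbind(intercept = 1, age = referent$age, weight = referent$weight)
  if (qr(X)$rank < 3L) stop("rank-deficient design: constant age or weight")
  fit <- stats::lm.fit(X, referent$bmi)
  stats::setNames(fit$coefficients, c("intercept", "age", "weight"))
}

#' Predict BMI from fitted coefficients
#' @param coefs Coefficients from [fit_bmi_predictor()].
#' @param covariates A tibble with columns `age` and `weight`.
#' @return Numeric vector of predicted BMI values.
#' @export
predict_bmi <- function(coefs, covariates) {
  coefs[["intercept"]] + coefs[["age"]] * covariates$age +
    coefs[["weight"]] * covariates$weight
}

#' Estimated inverse-probability weights
#'
#' Predicts BMI for each sampled individual from its age and weight, maps the
#' prediction to a population BMI decile, and inverts that decile's selection
#' probability. Prediction error can land an individual in a decile with zero
#' reference weight; such individuals receive a capped fallback weight equal
#' to the largest finite weight in the sample (reciprocal of the smallest
#' positive estimated probability), preserving the weight ordering without
#' creating infinities.
#'
#' Estimated probabilities are normalized by `p_normalizer`; since weighted
#' least squares is invariant to a common rescaling of the weights, this
#' affects only the reported scale (supplying the population-level normalizer
#' makes the weights directly comparable to [ipw_known()]).
#'
#' @param covariates Tibble with `age` and `weight` for the sampled
#'   individuals.
#' @param coefs BMI predictor coefficients from [fit_bmi_predictor()].
#' @param w Decile weight 10-vector of the sampled side's reference cohort.
#' @param decile_cuts Population decile cut points.
#' @param p_normalizer Normalizing constant for raw decile weights; defaults
#'   to the within-sample sum. To reproduce the scale of [ipw_known()], pass
#'   `sum(w[decile_index_of_population])` over the whole population.
#' @param fallback_weight Weight assigned to individuals whose predicted
#'   decile has zero reference weight; `NULL` (default) uses the largest
#'   finite weight in the sample.
#' @return Numeric vector of estimated inverse-probability weights.
#' @export
ipw_estimated <- function(covariates, coefs, w, decile_cuts,
                          p_normalizer = NULL, fallback_weight = NULL) {
  bmi_hat <- predict_bmi(coefs, covariates)
  p_raw <- w[decile_index(bmi_hat, decile_cuts)]
  if (is.null(p_normalizer)) p_normalizer <- sum(p_raw)
  if (p_normalizer <= 0) stop("no sampled individual maps to a positive-weight decile")
  p_hat <- p_raw / p_normalizer
  wts <- ifelse(p_hat > 0, 1 / p_hat, NA_real_)
  if (anyNA(wts)) {
    if (is.null(fallback_weight)) {
      if (all(is.na(wts))) stop("all estimated probabilities are zero")
      fallback_weight <- max(wts, na.rm = TRUE)
    }
    wts[is.na(wts)] <- fallback_weight
  }
  wts
}
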