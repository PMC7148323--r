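test_that("population deciles are equal-frequency, left-closed bins", {
  cuts <- population_deciles(1:100)
  expect_length(cuts, 9L)
  expect_true(all(diff(cuts) >= 0))
  counts <- tabulate(findInterval(1:100, cuts) + 1L, nbins = 10L)
  expect_equal(counts, rep(10L, 10L))
  expect_error(population_deciles(rep(1:5, 10)), "distinct")
})

test_that("empirical deciles agree with theoretical lognormal quantiles", {
  x <- withr::with_seed(4, exp(rnorm(1e5)))
  cuts <- population_deciles(x)
  theo <- exp(qnorm(seq(0.1, 0.9, 0.1)))
  expect_lt(max(abs(log(cuts) - log(theo))), 0.02)
})

test_that("decile weights count reference mass per population bin", {
  cuts <- population_deciles(1:100)
  # uniform draw from the population itself is the self-reference limit
  ref <- withr::with_seed(8, sample(1:100, 5000, replace = TRUE))
  expect_lt(max(abs(decile_weights(ref, cuts) - 0.1)), 0.02)

  expect_equal(decile_weights(rep(1, 7), cuts), c(1, rep(0, 9)))

  # 20-member reference, 5 values in each of deciles 1-4
  ref4 <- rep(c(5, 15, 25, 35), each = 5)
  expect_equal(decile_weights(ref4, cuts), c(rep(0.25, 4), rep(0, 6)))
  expect_error(decile_weights(numeric(0), cuts), "empty")
})

test_that("selection probabilities spread decile weights over individuals", {
  pop_bmi <- seq(0.5, 19.5, by = 1) # 20 individuals, 2 per decile of 1..20-ish
  cuts <- population_deciles(pop_bmi)
  w1 <- c(1, rep(0, 9))
  p <- selection_probabilities(pop_bmi, w1, cuts)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_equal(sort(unique(round(p, 12))), c(0, 0.5))
  expect_equal(sum(p == 0.5), 2L)

  p_unif <- selection_probabilities(pop_bmi, rep(0.1, 10), cuts)
  expect_equal(p_unif, rep(1 / 20, 20))
  expect_error(selection_probabilities(pop_bmi, rep(0, 10), cuts), "zero")
})

test_that("biased draws follow the selection probabilities", {
  p <- c(1, rep(0, 9))
  smp <- draw_biased_sample(p, 50, seed = 2)
  expect_true(all(smp$index == 1L))
  expect_true(all(smp$p_at_draw == 1))

  # multinomial frequency oracle: empirical rates within 4 binomial SEs
  p2 <- withr::with_seed(5, {v <- runif(40); v / sum(v)})
  big <- draw_biased_sample(p2, 1e6, seed = 3)
  freq <- tabulate(big$index, nbins = 40) / 1e6
  se <- sqrt(p2 * (1 - p2) / 1e6)
  expect_true(all(abs(freq - p2) < 4 * se + 1e-12))

  expect_identical(draw_biased_sample(p2, 100, seed = 4)$index,
                   draw_biased_sample(p2, 100, seed = 4)$index)
})

test_that("random splits give disjoint samples of the stated sizes", {
  split <- random_sample_split(100000, seed = 6)
  expect_equal(nrow(split$twas), 750L)
  expect_equal(nrow(split$gwas), 1500L)
  expect_length(intersect(split$twas$index, split$gwas$index), 0L)
  expect_equal(length(unique(c(split$twas$index, split$gwas$index))), 2250L)
  expect_error(random_sample_split(1000, n1 = 750, n2 = 1500), "exceeds")
})

test_that("known inverse-probability weights are reciprocals", {
  smp <- tibble::tibble(index = 1:3, p_at_draw = c(0.5, 0.25, 0.25))
  expect_equal(ipw_known(smp), c(2, 4, 4))
  expect_true(all(is.finite(ipw_known(smp))))
  expect_error(ipw_known(tibble::tibble(index = 1:3)), "no selection probabilities")

  # uniform probabilities: constant weights leave the stage-1 fit unchanged
  pop <- simulate_population(small_params(2000L), seed = 41)
  smp2 <- draw_biased_sample(rep(1 / 2000, 2000), 300, seed = 42)
  twas <- pop[smp2$index, ]
  f_w <- stage_one(twas, weights = ipw_known(smp2))
  f_u <- stage_one(twas)
  expect_equal(f_w$alpha1_hat, f_u$alpha1_hat, tolerance = 1e-10)
})

test_that("the BMI predictor is ordinary least squares on age and weight", {
  ref <- tibble::tibble(age = runif(50, 21, 70), weight = runif(50, 50, 120))
  ref$bmi <- 5 + 0.3 * ref$weight
  cf <- fit_bmi_predictor(ref)
  expect_equal(unname(cf), c(5, 0, 0.3), tolerance = 1e-8)

  bad <- tibble::tibble(age = rep(1, 10), weight = rep(2, 10), bmi = rnorm(10))
  expect_error(fit_bmi_predictor(bad), "rank-deficient")

  # out-of-sample predictability on a survey-like synthetic referent
  train <- sample_reference_bmi(cohort_spec("NHANES", "women"), size = 10000,
                                seed = 43)
  test <- sample_reference_bmi(cohort_spec("NHANES", "women"), size = 10000,
                               seed = 44)
  cf2 <- fit_bmi_predictor(train)
  r2 <- 1 - mean((test$bmi - predict_bmi(cf2, test))^2) / var(test$bmi)
  expect_gt(r2, 0.60)
  expect_lt(r2, 0.95)
})

test_that("estimated weights reduce to known weights under a perfect predictor", {
  pop <- simulate_population(small_params(20000L), seed = 45)
  cuts <- population_deciles(pop$bmi)
  ref <- sample_reference_bmi(cohort_spec("GTEx", "women"), seed = 46)
  w <- decile_weights(ref$bmi, cuts)
  p <- selection_probabilities(pop$bmi, w, cuts)
  smp <- draw_biased_sample(p, 750, seed = 47)

  # a "predictor" that returns observed BMI exactly
  perfect <- c(intercept = 0, age = 0, weight = 1)
  cov_perfect <- tibble::tibble(age = rep(0, 750), weight = pop$bmi[smp$index])
  total <- sum(w[findInterval(pop$bmi, cuts) + 1L])
  est <- ipw_estimated(cov_perfect, perfect, w, cuts, p_normalizer = total)
  expect_equal(est, ipw_known(smp), tolerance = 1e-12)

  # equal predicted deciles imply equal weights
  same_dec <- tibble::tibble(age = c(0, 0), weight = c(cuts[4] + 0.1, cuts[5] - 0.1))
  est2 <- ipw_estimated(same_dec, perfect, w, cuts)
  expect_equal(est2[1], est2[2])
})

test_that("estimated weights track known weights under the default predictor", {
  pop <- simulate_population(small_params(20000L), seed = 48)
  cuts <- population_deciles(pop$bmi)
  ref <- sample_reference_bmi(cohort_spec("GTEx", "women"), seed = 49)
  w <- decile_weights(ref$bmi, cuts)
  p <- selection_probabilities(pop$bmi, w, cuts)
  smp <- draw_biased_sample(p, 750, seed = 50)
  referent <- sample_reference_bmi(cohort_spec("NHANES", "women"), seed = 51)
  cf <- fit_bmi_predictor(referent)
  est <- ipw_estimated(pop[smp$index, c("age", "weight")], cf, w, cuts)
  # simulation oracle: rank agreement averages ~0.43 across replicates (decile
  # misclassification from BMI prediction error plus heavy ties); assert the
  # measured band rather than perfect fidelity
  rho <- cor(est, ipw_known(smp), method = "spearman")
  expect_gt(rho, 0.25)
  expect_lt(rho, 0.75)
})

test_that("shifting reference mass to lower deciles lowers sampled BMI", {
  pop <- simulate_population(small_params(20000L), seed = 52)
  cuts <- population_deciles(pop$bmi)
  # three nested reference profiles, increasingly bottom-heavy
  shifts <- list(rep(0.1, 10), c(rep(0.15, 6), rep(0.025, 4)),
                 c(rep(0.3, 3), 0.1, rep(0, 6)))
  means <- vapply(shifts, function(w) {
    p <- selection_probabilities(pop$bmi, w, cuts)
    smp <- draw_biased_sample(p, 2000, seed = 53)
    mean(pop$bmi[smp$index])
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})
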