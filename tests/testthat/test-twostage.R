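test_that("weighted OLS interpolates, is scale-invariant, and matches lm", {
  fit <- weighted_ols(cbind(1, c(0, 1)), c(0, 1))
  expect_equal(unname(fit$coefficients), c(0, 1), tolerance = 1e-12)

  X <- cbind(1, withr::with_seed(1, rnorm(30)))
  y <- withr::with_seed(2, rnorm(30))
  f0 <- weighted_ols(X, y)
  fc <- weighted_ols(X, y, weights = rep(7.5, 30))
  expect_equal(fc$coefficients, f0$coefficients, tolerance = 1e-12)
  expect_equal(fc$se, f0$se, tolerance = 1e-12)

  # classical SEs agree with lm
  ref <- stats::lm(y ~ X[, 2])
  expect_equal(unname(f0$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(f0$residual_sd, summary(ref)$sigma, tolerance = 1e-10)

  expect_error(weighted_ols(cbind(1, rep(2, 10)), rnorm(10)), "rank-deficient")
  expect_error(weighted_ols(matrix(rnorm(6), 2, 3), rnorm(2)), "fewer rows")
})

test_that("integer weights replicate rows exactly (replication oracle)", {
  for (s in 1:5) {
    withr::with_seed(100 + s, {
      X <- cbind(1, rnorm(5))
      y <- rnorm(5)
      k <- sample(1:4, 5, replace = TRUE)
    })
    fw <- weighted_ols(X, y, weights = k)
    frep <- weighted_ols(X[rep(1:5, k), ], y[rep(1:5, k)])
    expect_lt(max(abs(fw$coefficients - frep$coefficients)), 1e-8)
  }
})

test_that("stage 1 recovers the noiseless model and enforces sizes", {
  z1 <- c(0, 1, 2, 0, 1, 2)
  z2 <- c(0, 0, 1, 1, 2, 2)
  twas <- tibble::tibble(z1 = z1, z2 = z2, x = 10 + 0.1 * z1 + 0.2 * z2)
  fit <- stage_one(twas)
  expect_equal(c(fit$alpha0_hat, fit$alpha1_hat, fit$alpha2_hat),
               c(10, 0.1, 0.2), tolerance = 1e-10)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-8)
  expect_error(stage_one(twas[1:3, ]), "too small")

  td <- tidy(fit)
  expect_equal(td$estimate, c(10, 0.1, 0.2), tolerance = 1e-10)
  expect_equal(glance(fit)$weights_used, "none")
})

test_that("expression prediction is the stage-1 linear form", {
  fit <- structure(list(alpha0_hat = 10, alpha1_hat = 0.1, alpha2_hat = 0.2),
                   class = "stage_one_fit")
  expect_equal(predict_expression(fit, tibble::tibble(z1 = 0, z2 = 0)), 10)
  expect_equal(predict_expression(fit, tibble::tibble(z1 = 1, z2 = 2)), 10.5)
  # affine: increments are independent of the base genotype
  g <- tibble::tibble(z1 = c(0, 1), z2 = c(0, 0))
  d <- diff(predict_expression(fit, g))
  g2 <- tibble::tibble(z1 = c(1, 2), z2 = c(2, 2))
  expect_equal(diff(predict_expression(fit, g2)), d)
})

test_that("stage 2 fits the trait on predicted expression with a t-interval", {
  xhat <- c(9.8, 10, 10.2, 10.4, 9.9, 10.1)
  y <- 1.8 + 0.15 * xhat
  fit <- stage_two(xhat, y)
  expect_equal(fit$gamma1_hat, 0.15, tolerance = 1e-10)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-7)
  expect_equal(fit$ci_high - fit$gamma1_hat, fit$gamma1_hat - fit$ci_low,
               tolerance = 1e-12)
  expect_error(stage_two(rep(10, 6), rnorm(6)), "constant")
  expect_error(stage_two(xhat[1:2], y[1:2]), "too small")

  # CI matches confint on lm
  y2 <- y + withr::with_seed(3, rnorm(6, 0, 0.1))
  f2 <- stage_two(xhat, y2)
  ref <- stats::confint(stats::lm(y2 ~ xhat))
  expect_equal(c(f2$ci_low, f2$ci_high), unname(ref[2, ]), tolerance = 1e-10)
})

test_that("relative bias and coverage follow their defining formulas", {
  expect_equal(round(relative_bias(0.146, 0.15), 1), -2.7)
  expect_equal(round(relative_bias(0.295, 0.15), 1), 96.7)
  expect_equal(relative_bias(0.15, 0.15), 0)
  expect_equal(relative_bias(c(0.3, 0.075), 0.15), c(100, -50))
  expect_error(relative_bias(1, 0), "truth = 0")

  expect_true(ci_covers(0.1, 0.2, 0.15))
  expect_false(ci_covers(0.16, 0.2, 0.15))
  expect_true(ci_covers(0.15, 0.2, 0.15)) # closed endpoints
  expect_error(ci_covers(0.2, 0.1, 0.15))
})

test_that("mean predicted expression reports log2 and anti-log scales", {
  m <- mean_predicted_expression(rep(10, 5))
  expect_equal(m$mean_log2, 10)
  expect_equal(m$antilog2, 1024)
  x <- withr::with_seed(4, rnorm(50, 10))
  expect_equal(mean_predicted_expression(x + 2)$mean_log2,
               mean_predicted_expression(x)$mean_log2 + 2)
  expect_error(mean_predicted_expression(numeric(0)), "empty")
})

test_that("a population-level stage 1 makes the two-stage estimate unbiased", {
  params <- small_params(50000L)
  pop <- simulate_population(params, seed = 61)
  s1 <- stage_one(pop) # fit on the entire population
  est <- withr::with_seed(62, vapply(seq_len(500), function(i) {
    idx <- sample.int(nrow(pop), 1500)
    stage_two(predict_expression(s1, pop[idx, ]), pop$y[idx])$gamma1_hat
  }, numeric(1)))
  expect_lt(abs(mean(relative_bias(est, params$gamma1))), 2)
})

test_that("coverage is nominal with the true regressor, degraded with a predicted one", {
  params <- small_params(20000L)
  pop <- simulate_population(params, seed = 63)
  cover_true <- withr::with_seed(64, vapply(seq_len(500), function(i) {
    idx <- sample.int(nrow(pop), 1500)
    f <- stage_two(pop$x[idx], pop$y[idx])
    ci_covers(f$ci_low, f$ci_high, params$gamma1)
  }, logical(1)))
  expect_gte(mean(cover_true), 0.92)
  expect_lte(mean(cover_true), 0.98)

  cover_pred <- withr::with_seed(65, vapply(seq_len(500), function(i) {
    split <- random_sample_split(nrow(pop))
    s1 <- stage_one(pop[split$twas$index, ])
    f <- stage_two(predict_expression(s1, pop[split$gwas$index, ]),
                   pop$y[split$gwas$index])
    ci_covers(f$ci_low, f$ci_high, params$gamma1)
  }, logical(1)))
  expect_lt(mean(cover_pred), 0.90)
})

test_that("IPW with uniform probabilities leaves the two-stage mean unchanged", {
  params <- small_params(20000L)
  pop <- simulate_population(params, seed = 66)
  n <- nrow(pop)
  p_unif <- rep(1 / n, n)
  # with-replacement uniform draws, stage 1 weighted by 1/p
  est_w <- withr::with_seed(67, vapply(1:300, function(i) {
    smp <- draw_biased_sample(p_unif, 750)
    s1 <- stage_one(pop[smp$index, ], weights = ipw_known(smp))
    idx2 <- sample.int(n, 1500)
    stage_two(predict_expression(s1, pop[idx2, ]), pop$y[idx2])$gamma1_hat
  }, numeric(1)))
  # unweighted random-sampling scheme
  est_u <- withr::with_seed(68, vapply(1:300, function(i) {
    split <- random_sample_split(n)
    s1 <- stage_one(pop[split$twas$index, ])
    stage_two(predict_expression(s1, pop[split$gwas$index, ]),
              pop$y[split$gwas$index])$gamma1_hat
  }, numeric(1)))
  se_diff <- sqrt(var(est_w) / 300 + var(est_u) / 300)
  expect_lt(abs(mean(est_w) - mean(est_u)), 3 * se_diff)
})
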