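#' Generative parameters for the composite expression-trait model
#'
#' The composite model is
#' \deqn{x_i = \alpha_0 + z_{i1}\alpha_1 + z_{i2}\alpha_2 + \delta_i, \qquad
#'       y_i = \gamma_0 + x_i\gamma_1 + \epsilon_i,}
#' with two independent biallelic SNPs in Hardy-Weinberg equilibrium
#' (`z ~ Binomial(2, maf)`), `delta ~ N(0, sigma_delta^2)` and
#' `eps ~ N(0, sigma_eps^2)` independent of each other and of the genotypes.
#' `x` is single-gene expression on a log2-normalized scale; `y` is natural-log
#' BMI, so `bmi = exp(y)`.
#'
#' The defaults target a mean expression of `mu1 = 10.39` log2 units and a
#' mean log BMI of `mu2 = 3.36`. The trait intercept `gamma0` is not a free
#' parameter: it is derived per simulated population as
#' `gamma0 = mu2 - mean(x) * gamma1` (see [derive_gamma0()]), using the
#' realized mean of expression.
#'
#' The default per-allele effects `alpha1 = alpha2 = 0.2` are chosen for
#' internal consistency with the default intercept: with them,
#' `alpha0 = mu1 - 2 * maf * (alpha1 + alpha2) = 10.39 - 0.16 = 10.23`
#' exactly, so the expected mean expression equals `mu1`. Passing
#' `alpha0 = "formula"` always recomputes the intercept from this identity
#' (useful when changing the SNP effects or MAF). `alpha0` shifts are absorbed
#' by `gamma0` and do not affect slopes, relative bias or coverage.
#'
#' @param alpha0 Intercept of the genotype-expression model (log2 units), or
#'   the string `"formula"` for `mu1 - 2*maf*(alpha1 + alpha2)`.
#' @param alpha1,alpha2 Per-minor-allele SNP effects on expression (log2 units).
#' @param gamma1 Expression-trait effect (log BMI per log2 expression unit).
#' @param sigma_delta Expression residual sd (log2 units).
#' @param sigma_eps Trait residual sd (log BMI units).
#' @param maf Minor allele frequency shared by both SNPs, in (0, 0.5).
#' @param mu1 Target mean expression (log2 units); used only by the
#'   `"formula"` option for `alpha0`.
#' @param mu2 Target mean natural-log BMI.
#' @param pop_size Population size N.
#' @return A `dgp_params` object (named list).
#' @export
#' @examples
#' dgp_params()
#' dgp_params(alpha0 = "formula")$alpha0
dgp_params <- function(alpha0 = 10.23, alpha1 = 0.2, alpha2 = 0.2,
                       gamma1 = 0.15, sigma_delta = 1.6, sigma_eps = 0.065,
                       maf = 0.20, mu1 = 10.39, mu2 = 3.36,
                       pop_size = 100000L) {
  if (identical(alpha0, "formula")) {
    alpha0 <- mu1 - 2 * maf * (alpha1 + alpha2)
  }
  stopifnot(
    is.numeric(alpha0), sigma_delta > 0, sigma_eps > 0,
    maf > 0, maf < 0.5, pop_size >= 1
  )
  structure(
    list(alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2,
         gamma1 = gamma1, sigma_delta = sigma_delta, sigma_eps = sigma_eps,
         maf = maf, mu1 = mu1, mu2 = mu2, pop_size = as.integer(pop_size)),
    class = "dgp_params"
  )
}

#' @export
print.dgp_params <- function(x, ...) {
  cat("<dgp_params>\n")
  cat(sprintf("  expression: x = %.4g + %.3g*z1 + %.3g*z2 + N(0, %.3g^2)\n",
              x$alpha0, x$alpha1, x$alpha2, x$sigma_delta))
  cat(sprintf("  trait:      y = gamma0 + %.3g*x + N(0, %.3g^2),  gamma0 = %.3g - mean(x)*%.3g\n",
              x$gamma1, x$sigma_eps, x$mu2, x$gamma1))
  cat(sprintf("  genotypes:  two SNPs, Binomial(2, %.2g); N = %d\n",
              x$maf, x$pop_size))
  invisible(x)
}

#' Derive the trait intercept from the target mean log BMI
#'
#' `gamma0 = mu2 - xbar * gamma1`, where `xbar` is the realized mean of
#' expression in the simulated population. This pins the population mean of
#' natural-log BMI at `mu2` (up to the mean of the trait residuals).
#'
#' @param mu2 Target mean natural-log BMI.
#' @param xbar Realized mean expression (log2 units).
#' @param gamma1 Expression-trait effect.
#' @return The trait intercept `gamma0`.
#' @export
#' @examples
#' derive_gamma0(3.36, 10.39, 0.15) # 1.8015
derive_gamma0 <- function(mu2, xbar, gamma1) {
  mu2 - xbar * gamma1
}

#' Simulate a population under the composite model
#'
#' Draws genotypes, expression and trait for `params$pop_size` individuals,
#' then attaches age/weight/height covariates to the implied BMI values via
#' [attach_covariates()] (so estimated inverse-probability weights can be
#' exercised downstream). Draw order is fixed: z1, z2, delta, eps, covariates.
#'
#' @param params A [dgp_params()] object.
#' @param seed Optional integer seed (RNG-state preserving).
#' @return A tibble with columns `id`, `z1`, `z2`, `x`, `y`, `bmi`, `age`,
#'   `weight`, `height`, and attributes `params`, `gamma0`, `seed`.
#' @export
#' @examples
#' pop <- simulate_population(dgp_params(pop_size = 1000), seed = 1)
#' mean(pop$x)
simulate_population <- function(params = dgp_params(), seed = NULL) {
  stopifnot(inherits(params, "dgp_params"))
  n <- params$pop_size
  draw <- function() {
    z1 <- stats::rbinom(n, 2L, params$maf)
    z2 <- stats::rbinom(n, 2L, params$maf)
    delta <- stats::rnorm(n, 0, params$sigma_delta)
    x <- params$alpha0 + params$alpha1 * z1 + params$alpha2 * z2 + delta
    gamma0 <- derive_gamma0(params$mu2, mean(x), params$gamma1)
    eps <- stats::rnorm(n, 0, params$sigma_eps)
    y <- gamma0 + params$gamma1 * x + eps
    bmi <- exp(y)
    cov <- attach_covariates(bmi)
    pop <- tibble::tibble(
      id = seq_len(n), z1 = z1, z2 = z2, x = x, y = y, bmi = bmi,
      age = cov$age, weight = cov$weight, height = cov$height
    )
    attr(pop, "gamma0") <- gamma0
    pop
  }
  pop <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  attr(pop, "params") <- params
  attr(pop, "seed") <- seed
  pop
}

#' Moment summary of a simulated population
#'
#' Means and variances of genotypes, expression, trait and BMI. Also reports
#' `2^mean(x)` as expression on the anti-log scale; note this is a reporting
#' convention only (the mean of `2^x` is not `2^mean(x)` for noisy `x`), and
#' anti-log-scale abundance values should not be compared across conventions.
#'
#' @param pop A population tibble from [simulate_population()].
#' @return A one-row tibble of summary moments.
#' @export
population_summary <- function(pop) {
  if (nrow(pop) == 0) stop("empty population")
  v <- function(u) if (length(u) > 1) stats::var(u) else 0
  tibble::tibble(
    n = nrow(pop),
    mean_z1 = mean(pop$z1), var_z1 = v(pop$z1),
    mean_z2 = mean(pop$z2), var_z2 = v(pop$z2),
    mean_x = mean(pop$x), var_x = v(pop$x),
    mean_y = mean(pop$y), var_y = v(pop$y),
    mean_bmi = mean(pop$bmi), var_bmi = v(pop$bmi),
    antilog2_mean_x = 2^mean(pop$x)
  )
}
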