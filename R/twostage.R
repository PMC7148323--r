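#' Weighted ordinary least squares with classical standard errors
#'
#' Thin shared estimator for both stages: minimizes the (weighted) residual
#' sum of squares and reports classical homoskedastic standard errors,
#' `sigma^2 (X'WX)^{-1}` with `sigma^2 = RSS_w / (n - p)`. With all weights
#' equal it reduces exactly to unweighted OLS.
#'
#' @param X Design matrix (including the intercept column if wanted).
#' @param y Response vector.
#' @param weights Optional nonnegative observation weights.
#' @return A list with `coefficients`, `se`, `residual_sd`, `df_residual`.
#' @export
#' @examples
#' weighted_ols(cbind(1, c(0, 1)), c(0, 1))$coefficients
weighted_ols <- function(X, y, weights = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < p) stop("fewer rows than columns")
  fit <- if (is.null(weights)) {
    stats::lm.fit(X, y)
  } else {
    stopifnot(length(weights) == n, all(weights >= 0))
    stats::lm.wfit(X, y, weights)
  }
  if (fit$rank < p) stop("rank-deficient design matrix")
  res <- fit$residuals
  rss <- if (is.null(weights)) sum(res^2) else sum(weights * res^2)
  df <- n - p
  s2 <- if (df > 0) rss / df else 0
  # (X'WX)^{-1} from the QR factorization of sqrt(W) X, undoing column pivoting
  Rinv <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  XtXinv <- matrix(NA_real_, p, p)
  XtXinv[fit$qr$pivot, fit$qr$pivot] <- Rinv
  se <- sqrt(pmax(diag(XtXinv) * s2, 0))
  cf <- fit$coefficients
  names(se) <- names(cf)
  list(coefficients = cf, se = se, residual_sd = sqrt(s2), df_residual = df)
}

#' Stage 1: regress expression on genotype in the TWAS sample
#'
#' Fits `x ~ z1 + z2` by (optionally inverse-probability-weighted) least
#' squares. The fitted intercept and SNP coefficients define the expression
#' prediction model applied to the GWAS sample.
#'
#' @param twas A tibble with columns `z1`, `z2`, `x`.
#' @param weights Optional inverse-probability weights (from [ipw_known()] or
#'   [ipw_estimated()]).
#' @param weights_used Label recorded on the fit: `"none"`, `"known"` or
#'   `"estimated"`.
#' @return A `stage_one_fit` object with elements `alpha0_hat`, `alpha1_hat`,
#'   `alpha2_hat`, `residual_sd`, `weights_used`, `n1`.
#' @export
stage_one <- function(twas, weights = NULL,
                      weights_used = if (is.null(weights)) "none" else "known") {
  stopifnot(all(c("z1", "z2", "x") %in% names(twas)))
  if (nrow(twas) < 4) stop("stage-1 sample too small (need n1 >= 4)")
  X <- cbind(`(Intercept)` = 1, z1 = twas$z1, z2 = twas$z2)
  fit <- weighted_ols(X, twas$x, weights)
  structure(
    list(alpha0_hat = unname(fit$coefficients[1]),
         alpha1_hat = unname(fit$coefficients[2]),
         alpha2_hat = unname(fit$coefficients[3]),
         se = fit$se,
         residual_sd = fit$residual_sd,
         weights_used = weights_used,
         n1 = nrow(twas)),
    class = "stage_one_fit"
  )
}

#' Predict expression in the GWAS sample from a stage-1 fit
#'
#' `xhat = alpha0_hat + z1 * alpha1_hat + z2 * alpha2_hat`; a pure linear
#' prediction with no residual noise added (single mean imputation).
#'
#' @param fit A `stage_one_fit`.
#' @param gwas A tibble with columns `z1`, `z2`.
#' @return Numeric vector of predicted expression values (log2 units).
#' @export
predict_expression <- function(fit, gwas) {
  stopifnot(inherits(fit, "stage_one_fit"))
  fit$alpha0_hat + fit$alpha1_hat * gwas$z1 + fit$alpha2_hat * gwas$z2
}

#' Stage 2: regress the trait on predicted expression
#'
#' Unweighted OLS of `y` on `xhat` with a t-based 95% confidence interval
#' (`n2 - 2` degrees of freedom, classical standard errors). The slope is the
#' two-stage estimate of the expression-trait association.
#'
#' @param xhat Predicted expression in the GWAS sample.
#' @param y Trait values (natural-log BMI).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A `stage_two_fit` object with `gamma0_hat`, `gamma1_hat`,
#'   `se_gamma1`, `ci_low`, `ci_high`, `ci_length`, `n2`, `xhat_mean`.
#' @export
stage_two <- function(xhat, y, conf_level = 0.95) {
  n2 <- length(xhat)
  if (n2 < 3) stop("stage-2 sample too small (need n2 >= 3)")
  if (stats::sd(xhat) == 0) stop("predicted expression is constant: degenerate instrument signal")
  X <- cbind(`(Intercept)` = 1, xhat = xhat)
  fit <- weighted_ols(X, y)
  g1 <- unname(fit$coefficients[2])
  se <- unname(fit$se[2])
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n2 - 2)
  structure(
    list(gamma0_hat = unname(fit$coefficients[1]),
         gamma1_hat = g1,
         se_gamma1 = se,
         ci_low = g1 - tq * se,
         ci_high = g1 + tq * se,
         ci_length = 2 * tq * se,
         residual_sd = fit$residual_sd,
         n2 = n2,
         xhat_mean = mean(xhat)),
    class = "stage_two_fit"
  )
}

#' Relative bias of an estimate, in percent
#'
#' `100 * (estimate - truth) / truth`.
#'
#' @param estimate Estimated value(s).
#' @param truth True parameter value (nonzero).
#' @return Relative bias in percent (vectorized over `estimate`).
#' @export
#' @examples
#' relative_bias(0.146, 0.15) # -2.67
relative_bias <- function(estimate, truth) {
  if (any(truth == 0)) stop("relative bias undefined for truth = 0")
  100 * (estimate - truth) / truth
}

#' Does a confidence interval cover the truth?
#'
#' Closed-interval convention: endpoints count as covering.
#'
#' @param ci_low,ci_high Interval endpoints, `ci_low <= ci_high`.
#' @param truth True parameter value.
#' @return Logical.
#' @export
ci_covers <- function(ci_low, ci_high, truth) {
  stopifnot(all(ci_low <= ci_high))
  ci_low <= truth & truth <= ci_high
}

#' Mean predicted expression on log2 and anti-log scales
#'
#' Reports the arithmetic mean of predicted log2 expression and its base-2
#' anti-log. The anti-log is a reporting convention only: `2^mean(xhat)` is
#' the geometric-mean abundance, not the mean abundance, so values on this
#' scale are indicative rather than exactly comparable to raw-abundance
#' summaries.
#'
#' @param xhat Non-empty numeric vector of predicted log2 expression.
#' @return A one-row tibble with `mean_log2` and `antilog2`.
#' @export
mean_predicted_expression <- function(xhat) {
  if (length(xhat) == 0) stop("empty predicted-expression vector")
  m <- mean(xhat)
  tibble::tibble(mean_log2 = m, antilog2 = 2^m)
}

#' @export
print.stage_one_fit <- function(x, ...) {
  cat("<stage_one_fit> x ~ z1 + z2, n1 =", x$n1,
      "| weights:", x$weights_used, "\n")
  cat(sprintf("  alpha0_hat = %.4f, alpha1_hat = %.4f, alpha2_hat = %.4f, residual sd = %.3f\n",
              x$alpha0_hat, x$alpha1_hat, x$alpha2_hat, x$residual_sd))
  invisible(x)
}

#' @export
print.stage_two_fit <- function(x, ...) {
  cat("<stage_two_fit> y ~ xhat, n2 =", x$n2, "\n")
  cat(sprintf("  gamma1_hat = %.4f (se %.4f), 95%% CI [%.4f, %.4f]\n",
              x$gamma1_hat, x$se_gamma1, x$ci_low, x$ci_high))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stage-1 fit into one row per coefficient
#' @param x A `stage_one_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @export
tidy.stage_one_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "z1", "z2"),
    estimate = c(x$alpha0_hat, x$alpha1_hat, x$alpha2_hat),
    std.error = unname(x$se)
  )
}

#' One-row summary of a stage-1 fit
#' @param x A `stage_one_fit`.
#' @param ... Unused.
#' @export
glance.stage_one_fit <- function(x, ...) {
  tibble::tibble(residual_sd = x$residual_sd, n1 = x$n1,
                 weights_used = x$weights_used)
}

#' Tidy a stage-2 fit into one row per coefficient
#' @param x A `stage_two_fit`.
#' @param ... Unused.
#' @export
tidy.stage_two_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "xhat"),
    estimate = c(x$gamma0_hat, x$gamma1_hat),
    std.error = c(NA_real_, x$se_gamma1),
    conf.low = c(NA_real_, x$ci_low),
    conf.high = c(NA_real_, x$ci_high)
  )
}

#' One-row summary of a stage-2 fit
#' @param x A `stage_two_fit`.
#' @param ... Unused.
#' @export
glance.stage_two_fit <- function(x, ...) {
  tibble::tibble(
    gamma1_hat = x$gamma1_hat, se_gamma1 = x$se_gamma1,
    ci_low = x$ci_low, ci_high = x$ci_high, ci_length = x$ci_length,
    xhat_mean = x$xhat_mean, n2 = x$n2
  )
}
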