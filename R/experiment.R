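#' Configure a sampling scenario
#'
#' The four study scenarios differ only in how the TWAS (expression) and GWAS
#' (trait) samples are drawn from the simulated population:
#' \describe{
#'   \item{RS}{both samples drawn at random (no selection bias);}
#'   \item{GTEx-RS}{TWAS drawn with GTEx-mimicking decile weights, GWAS at
#'     random;}
#'   \item{GTEx-CRIC}{TWAS GTEx-weighted, GWAS CRIC-weighted;}
#'   \item{GTEx-GENE}{TWAS GTEx-weighted, GWAS GENE-weighted.}
#' }
#' Inverse probability weighting (`ipw`) applies to the stage-1 fit only and
#' requires a biased TWAS side.
#'
#' @param scenario One of `"RS"`, `"GTEx-RS"`, `"GTEx-CRIC"`, `"GTEx-GENE"`,
#'   or `"custom"` (references supplied explicitly).
#' @param twas_reference,gwas_reference [cohort_spec()] objects driving the
#'   biased draws, or `NULL` for random sampling on that side. For the named
#'   scenarios these default to the built-in women's cohort rows.
#' @param ipw `"none"`, `"known"` or `"estimated"`.
#' @param referent [cohort_spec()] used to fit the BMI predictor when
#'   `ipw = "estimated"` (default: built-in NHANES women).
#' @param n1,n2 TWAS and GWAS sample sizes.
#' @param replicates Number of Monte-Carlo replicates.
#' @param base_seed Integer seed from which per-replicate seeds are derived.
#' @param params [dgp_params()] for the population model.
#' @param regenerate_population If `TRUE` (default) a fresh population is
#'   simulated for every replicate; if `FALSE` one population is generated
#'   from `base_seed` and shared by all replicates (fixed-population mode).
#' @param fixed_cohorts If `TRUE`, reference-cohort samples are drawn once and
#'   reused; by default they are regenerated each replicate at the published
#'   cohort sizes, so small-cohort weight noise propagates.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(scenario = c("RS", "GTEx-RS", "GTEx-CRIC",
                                         "GTEx-GENE", "custom"),
                            twas_reference = NULL, gwas_reference = NULL,
                            ipw = c("none", "known", "estimated"),
                            referent = NULL,
                            n1 = 750, n2 = 1500,
                            replicates = 2000, base_seed = 1L,
                            params = dgp_params(),
                            regenerate_population = TRUE,
                            fixed_cohorts = FALSE) {
  scenario <- match.arg(scenario)
  ipw <- match.arg(ipw)
  tab <- NULL
  need <- function(cohort) {
    if (is.null(tab)) tab <<- builtin_cohort_table()
    cohort_spec(cohort, "women", table = tab)
  }
  if (scenario == "RS") {
    if (!is.null(twas_reference) || !is.null(gwas_reference)) {
      stop("RS takes no reference cohorts")
    }
  } else if (scenario == "GTEx-RS") {
    if (is.null(twas_reference)) twas_reference <- need("GTEx")
    if (!is.null(gwas_reference)) stop("GTEx-RS draws the GWAS sample at random")
  } else if (scenario %in% c("GTEx-CRIC", "GTEx-GENE")) {
    if (is.null(twas_reference)) twas_reference <- need("GTEx")
    if (is.null(gwas_reference)) {
      gwas_reference <- need(sub("GTEx-", "", scenario))
    }
  }
  if (ipw != "none" && is.null(twas_reference)) {
    stop("inverse probability weighting requires a biased TWAS side")
  }
  if (ipw == "estimated" && is.null(referent)) referent <- need("NHANES")
  structure(
    list(scenario = scenario, twas_reference = twas_reference,
         gwas_reference = gwas_reference, ipw = ipw, referent = referent,
         n1 = n1, n2 = n2, replicates = as.integer(replicates),
         base_seed = as.integer(base_seed), params = params,
         regenerate_population = regenerate_population,
         fixed_cohorts = fixed_cohorts),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  ref <- function(r) if (is.null(r)) "random" else paste0(r$cohort, "/", r$sex)
  cat("<scenario_config> ", x$scenario, " | TWAS: ", ref(x$twas_reference),
      " | GWAS: ", ref(x$gwas_reference), " | IPW: ", x$ipw, "\n", sep = "")
  cat(sprintf("  n1 = %d, n2 = %d, replicates = %d, base_seed = %d, population: %s\n",
              x$n1, x$n2, x$replicates, x$base_seed,
              if (x$regenerate_population) "regenerated per replicate" else "fixed"))
  invisible(x)
}

# precompute the per-population quantities every replicate needs
population_context <- function(pop) {
  cuts <- population_deciles(pop$bmi)
  list(decile_cuts = cuts, pop_decile = decile_index(pop$bmi, cuts))
}

# draw one side's sample (indices into pop) under the configured scheme;
# returns list(index, p_at_draw or NULL, w or NULL)
draw_side <- function(pop, ctx, reference, size, ref_sample = NULL) {
  if (is.null(reference)) stop("draw_side called without a reference cohort")
  if (is.null(ref_sample)) ref_sample <- sample_reference_bmi(reference)
  w <- decile_weights(ref_sample$bmi, ctx$decile_cuts)
  p_raw <- w[ctx$pop_decile]
  total <- sum(p_raw)
  if (total <= 0) stop("no population member falls in a positive-weight decile")
  p <- p_raw / total
  idx <- sample.int(nrow(pop), size, replace = TRUE, prob = p)
  list(index = idx, p_at_draw = p[idx], w = w, p_total = total)
}

#' Run one Monte-Carlo replicate of a scenario
#'
#' Draws the TWAS and GWAS samples per the scenario's scheme, fits stage 1
#' (with IPW if configured), predicts expression in the GWAS sample, fits
#' stage 2 and computes the per-replicate metrics. All randomness for the
#' replicate (cohort regeneration, sample draws) comes from `seed`; the draw
#' order is cohorts (TWAS reference, GWAS reference, IPW referent), then the
#' TWAS draw, then the GWAS draw.
#'
#' @param config A [scenario_config()].
#' @param pop A population tibble from [simulate_population()]. If `NULL` a
#'   fresh population is simulated inside the replicate (first in draw order).
#' @param seed Integer seed for this replicate.
#' @param replicate_id Identifier recorded in the output row.
#' @param ctx Optional precomputed population context (internal use).
#' @param cohort_samples Optional list with `twas`, `gwas`, `referent`
#'   reference samples for fixed-cohort mode.
#' @return A one-row tibble with stage-1 and stage-2 estimates, the 95% CI,
#'   relative-bias metrics and the coverage indicator.
#' @export
run_replicate <- function(config, pop = NULL, seed = 1L, replicate_id = 1L,
                          ctx = NULL, cohort_samples = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  withr::with_seed(seed, {
    if (is.null(pop)) {
      pop <- simulate_population(config$params)
      ctx <- NULL
    }
    if (is.null(ctx)) ctx <- population_context(pop)

    twas_ref <- gwas_ref <- NULL
    if (!is.null(config$twas_reference)) {
      twas_ref <- cohort_samples$twas %||% sample_reference_bmi(config$twas_reference)
    }
    if (!is.null(config$gwas_reference)) {
      gwas_ref <- cohort_samples$gwas %||% sample_reference_bmi(config$gwas_reference)
    }

    if (is.null(config$twas_reference) && is.null(config$gwas_reference)) {
      split <- random_sample_split(nrow(pop), config$n1, config$n2)
      twas_idx <- split$twas$index
      gwas_idx <- split$gwas$index
      twas_p <- NULL
    } else {
      side1 <- draw_side(pop, ctx, config$twas_reference, config$n1, twas_ref)
      twas_idx <- side1$index
      twas_p <- side1$p_at_draw
      if (is.null(config$gwas_reference)) {
        gwas_idx <- sample.int(nrow(pop), config$n2, replace = FALSE)
      } else {
        side2 <- draw_side(pop, ctx, config$gwas_reference, config$n2, gwas_ref)
        gwas_idx <- side2$index
      }
    }

    twas <- pop[twas_idx, c("z1", "z2", "x", "age", "weight")]
    gwas <- pop[gwas_idx, c("z1", "z2", "y")]

    # the IPW referent cohort is drawn after the sample draws, so runs that
    # differ only in the ipw setting see identical TWAS/GWAS samples under a
    # shared seed (the weighting comparison is then paired)
    wts <- switch(config$ipw,
      none = NULL,
      known = 1 / twas_p,
      estimated = {
        referent <- cohort_samples$referent %||%
          sample_reference_bmi(config$referent)
        coefs <- fit_bmi_predictor(referent)
        ipw_estimated(twas, coefs, side1$w, ctx$decile_cuts,
                      p_normalizer = side1$p_total)
      }
    )
    s1 <- stage_one(twas, weights = wts, weights_used = config$ipw)
    xhat <- predict_expression(s1, gwas)
    s2 <- stage_two(xhat, gwas$y)

    p <- config$params
    truth_alpha <- c(p$alpha0, p$alpha1, p$alpha2)
    est_alpha <- c(s1$alpha0_hat, s1$alpha1_hat, s1$alpha2_hat)
    rb_alpha <- relative_bias(est_alpha, truth_alpha)
    tibble::tibble(
      replicate = as.integer(replicate_id), seed = as.integer(seed),
      alpha0_hat = est_alpha[1], alpha1_hat = est_alpha[2],
      alpha2_hat = est_alpha[3], stage1_residual_sd = s1$residual_sd,
      gamma0_hat = s2$gamma0_hat, gamma1_hat = s2$gamma1_hat,
      se_gamma1 = s2$se_gamma1, ci_low = s2$ci_low, ci_high = s2$ci_high,
      ci_length = s2$ci_length, xhat_mean = s2$xhat_mean,
      xhat_sd = stats::sd(xhat),
      rel_bias_gamma1 = relative_bias(s2$gamma1_hat, p$gamma1),
      covered = ci_covers(s2$ci_low, s2$ci_high, p$gamma1),
      rel_bias_alpha0 = rb_alpha[1], rel_bias_alpha1 = rb_alpha[2],
      rel_bias_alpha2 = rb_alpha[3]
    )
  })
}

#' Run a full Monte-Carlo scenario
#'
#' Executes `config$replicates` independent replicates with per-replicate
#' seeds derived reproducibly from `config$base_seed`, and aggregates them
#' with [summarize_scenario()].
#'
#' @param config A [scenario_config()].
#' @param progress If `TRUE`, log replicate progress to standard error.
#' @return A `scenario_result`: list with `config`, `replicates` (one row per
#'   replicate, see [run_replicate()]) and `summary` (one row, see
#'   [summarize_scenario()]). `tidy()` returns the replicate table, `glance()`
#'   the summary row.
#' @export
#' @examples
#' cfg <- scenario_config("RS", replicates = 5, base_seed = 7,
#'                        params = dgp_params(pop_size = 5000),
#'                        regenerate_population = FALSE)
#' res <- run_scenario(cfg)
#' glance(res)
run_scenario <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  R <- config$replicates
  seeds <- withr::with_seed(config$base_seed,
                            sample.int(2147483646L, R + 2L))
  pop <- NULL; ctx <- NULL; cohorts <- NULL
  if (!config$regenerate_population) {
    pop <- simulate_population(config$params, seed = seeds[R + 1L])
    ctx <- population_context(pop)
  }
  if (config$fixed_cohorts) {
    cohorts <- withr::with_seed(seeds[R + 2L], list(
      twas = if (!is.null(config$twas_reference))
        sample_reference_bmi(config$twas_reference),
      gwas = if (!is.null(config$gwas_reference))
        sample_reference_bmi(config$gwas_reference),
      referent = if (config$ipw == "estimated")
        sample_reference_bmi(config$referent)
    ))
  }
  rows <- vector("list", R)
  for (r in seq_len(R)) {
    rows[[r]] <- run_replicate(config, pop = pop, seed = seeds[r],
                               replicate_id = r, ctx = ctx,
                               cohort_samples = cohorts)
    if (progress && r %% 200 == 0) {
      message(config$scenario, " [", config$ipw, "]: replicate ", r, "/", R)
    }
  }
  replicates <- dplyr::bind_rows(rows)
  structure(
    list(config = config, replicates = replicates,
         summary = summarize_scenario(replicates, config$params$gamma1,
                                      label = config$scenario,
                                      ipw = config$ipw)),
    class = "scenario_result"
  )
}

#' Aggregate replicate results into a scenario summary
#'
#' The Monte-Carlo summary reported per scenario: mean estimate, mean/median
#' relative bias with the interquartile range (25th and 75th percentiles,
#' type-7 linear interpolation), mean 95% CI length, coverage, per-coefficient
#' stage-1 mean relative bias, and the across-replicate mean and sd of mean
#' predicted expression (log2 and base-2 anti-log of the mean).
#'
#' @param replicates Replicate tibble from [run_replicate()] rows.
#' @param truth True expression-trait effect (gamma1).
#' @param label,ipw Labels carried into the output row.
#' @return A one-row tibble.
#' @export
summarize_scenario <- function(replicates, truth, label = NA_character_,
                               ipw = NA_character_) {
  reps <- replicates
  if (nrow(reps) == 0) stop("no replicates to summarize")
  rb <- reps$rel_bias_gamma1
  q <- unname(stats::quantile(rb, c(0.25, 0.75), type = 7))
  tibble::tibble(
    scenario = label, ipw = ipw, replicates = nrow(reps),
    mean_estimate = mean(reps$gamma1_hat),
    mean_rel_bias = mean(rb),
    median_rel_bias = stats::median(rb),
    iqr_lo = q[1], iqr_hi = q[2],
    mean_ci_length = mean(reps$ci_length),
    coverage = mean(reps$covered),
    mean_rel_bias_alpha0 = mean(reps$rel_bias_alpha0),
    mean_rel_bias_alpha1 = mean(reps$rel_bias_alpha1),
    mean_rel_bias_alpha2 = mean(reps$rel_bias_alpha2),
    xhat_mean_log2 = mean(reps$xhat_mean),
    xhat_sd_log2 = stats::sd(reps$xhat_mean),
    xhat_mean_antilog2 = 2^mean(reps$xhat_mean)
  )
}

#' Per-coefficient stage-1 relative-bias summaries
#'
#' Mean, median and interquartile range of the relative bias of the stage-1
#' intercept and SNP coefficients across replicates.
#'
#' @param replicates Replicate tibble (or a `scenario_result`).
#' @return A tibble with one row per coefficient.
#' @export
stage_one_bias_table <- function(replicates) {
  if (inherits(replicates, "scenario_result")) replicates <- replicates$replicates
  if (nrow(replicates) == 0) stop("no replicates")
  replicates |>
    dplyr::select(dplyr::all_of(c("rel_bias_alpha0", "rel_bias_alpha1",
                                  "rel_bias_alpha2"))) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "coefficient",
                        names_prefix = "rel_bias_", values_to = "rel_bias") |>
    dplyr::group_by(.data$coefficient) |>
    dplyr::summarise(
      mean = mean(.data$rel_bias),
      median = stats::median(.data$rel_bias),
      iqr_lo = unname(stats::quantile(.data$rel_bias, 0.25, type = 7)),
      iqr_hi = unname(stats::quantile(.data$rel_bias, 0.75, type = 7)),
      .groups = "drop"
    )
}

#' Compare two BMI distributions
#'
#' Two-sample Kolmogorov-Smirnov test and two-sided Wilcoxon rank-sum test,
#' the pair of nonparametric checks used to ask whether two cohorts plausibly
#' come from the same BMI distribution.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return A one-row tibble with `ks_stat`, `ks_p`, `ranksum_stat`,
#'   `ranksum_p`.
#' @export
compare_distributions <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0) stop("empty sample")
  ks <- suppressWarnings(stats::ks.test(sample_a, sample_b))
  wrs <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                             alternative = "two.sided"))
  tibble::tibble(
    ks_stat = unname(ks$statistic), ks_p = ks$p.value,
    ranksum_stat = unname(wrs$statistic), ranksum_p = wrs$p.value
  )
}

#' Compare synthetic cohorts to a referent cohort, by sex
#'
#' Regenerates each cohort's synthetic BMI sample at its published size and
#' applies [compare_distributions()] against the referent cohort of the same
#' sex, mirroring the published cohort-comparison table on synthetic data.
#'
#' @param table Cohort table in the [builtin_cohort_table()] schema.
#' @param referent_cohort Name of the referent cohort (default `"NHANES"`).
#' @param seed Integer seed for the synthetic samples.
#' @return A tibble with one row per non-referent (cohort, sex) pair.
#' @export
compare_cohorts_to_referent <- function(table = builtin_cohort_table(),
                                        referent_cohort = "NHANES",
                                        seed = 1L) {
  withr::with_seed(seed, {
    rows <- table[table$cohort != referent_cohort, c("cohort", "sex")]
    purrr::pmap_dfr(rows, function(cohort, sex) {
      ref <- sample_reference_bmi(cohort_spec(referent_cohort, sex, table = table))
      smp <- sample_reference_bmi(cohort_spec(cohort, sex, table = table))
      dplyr::bind_cols(tibble::tibble(cohort = cohort, sex = sex),
                       compare_distributions(smp$bmi, ref$bmi))
    })
  })
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> ", x$config$scenario, " | IPW: ", x$config$ipw,
      " | ", nrow(x$replicates), " replicates\n", sep = "")
  s <- x$summary
  cat(sprintf("  mean gamma1_hat = %.3f, mean relative bias = %.1f%%, mean CI length = %.3f, coverage = %.3f\n",
              s$mean_estimate, s$mean_rel_bias, s$mean_ci_length, s$coverage))
  invisible(x)
}

#' Replicate-level results of a scenario
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @return The replicate tibble.
#' @export
tidy.scenario_result <- function(x, ...) x$replicates

#' One-row Monte-Carlo summary of a scenario
#' @param x A `scenario_result`.
#' @param ... Unused.
#' @export
glance.scenario_result <- function(x, ...) x$summary

#' @importFrom rlang %||% .data
NULL
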