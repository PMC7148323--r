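#' BMI category boundaries (kg/m^2)
#'
#' The four conventional adult BMI categories: underweight, normal weight,
#' overweight, obese. Bins are left-closed, right-open, so a BMI of exactly
#' 18.5 falls in the normal-weight category.
#' @keywords internal
bmi_category_breaks <- c(18.5, 25.0, 30.0)

bmi_category_labels <- c("<18.5", "18.5-24.9", "25.0-29.9", ">=30.0")

#' Default within-category BMI distributions
#'
#' Reference cohorts are published only as category proportions, so the shape
#' of BMI inside each category is a modelling choice: uniform within the three
#' bounded categories and a shifted exponential (mean excess 5 kg/m^2) above
#' 30 to capture the right-tail skew of obesity.
#'
#' @return A list of four distribution rules, one per BMI category.
#' @export
default_within_category_model <- function() {
  list(
    list(type = "uniform", min = 15.0, max = 18.5),
    list(type = "uniform", min = 18.5, max = 25.0),
    list(type = "uniform", min = 25.0, max = 30.0),
    list(type = "shifted_exponential", shift = 30.0, mean = 5.0)
  )
}

#' Built-in reference-cohort BMI category table
#'
#' Published four-category BMI proportions and sample sizes for the NHANES,
#' GTEx, CRIC and GENE cohorts (White/non-Hispanic, ages 21-70), by sex.
#' Proportions are renormalized to sum to exactly 1 (printed rows can sum to
#' 0.999 or 1.001 by rounding).
#'
#' @return A tibble with columns `cohort`, `sex`, `n`, `p_under`, `p_normal`,
#'   `p_over`, `p_obese`.
#' @export
#' @examples
#' builtin_cohort_table()
builtin_cohort_table <- function() {
  path <- system.file("extdata", "cohort_bmi_categories.tsv",
                      package = "twasbias", mustWork = TRUE)
  read_cohort_table(path)
}

#' Read a cohort BMI category table from TSV
#'
#' Accepts user-supplied cohort specifications in the same schema as
#' [builtin_cohort_table()]: columns `cohort`, `sex`, `n`, `p_under`,
#' `p_normal`, `p_over`, `p_obese`. Proportions are renormalized on load.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble in the [builtin_cohort_table()] schema.
#' @export
read_cohort_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("cohort", "sex", "n", "p_under", "p_normal", "p_over", "p_obese")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("cohort table is missing columns: ", paste(missing, collapse = ", "))
  }
  pcols <- c("p_under", "p_normal", "p_over", "p_obese")
  pm <- as.matrix(tab[pcols])
  if (any(pm < 0) || any(pm > 1)) {
    stop("cohort proportions must lie in [0, 1]")
  }
  if (any(tab$n <= 0)) stop("cohort sizes must be positive")
  tab[pcols] <- pm / rowSums(pm)
  tibble::as_tibble(tab)
}

#' Look up a single cohort specification
#'
#' @param cohort Cohort name (e.g. `"GTEx"`); case-sensitive.
#' @param sex `"women"` or `"men"`.
#' @param table A cohort table in the [builtin_cohort_table()] schema;
#'   defaults to the built-in table.
#' @param within_category_model Distribution rules for BMI inside each
#'   category; see [default_within_category_model()].
#' @return A `cohort_spec` object: a list with `cohort`, `sex`, `n`,
#'   `proportions` (4-vector summing to 1) and `within_category_model`.
#' @export
#' @examples
#' cohort_spec("GTEx", "women")
cohort_spec <- function(cohort, sex, table = builtin_cohort_table(),
                        within_category_model = default_within_category_model()) {
  hit <- table$cohort == cohort & table$sex == sex
  if (sum(hit) != 1) {
    keys <- paste0("(", table$cohort, ", ", table$sex, ")", collapse = ", ")
    stop("unknown cohort key (", cohort, ", ", sex, "); valid keys: ", keys)
  }
  row <- table[hit, ]
  p <- as.numeric(row[c("p_under", "p_normal", "p_over", "p_obese")])
  stopifnot(abs(sum(p) - 1) < 1e-9)
  structure(
    list(
      cohort = cohort,
      sex = sex,
      n = as.integer(row$n),
      proportions = p,
      within_category_model = within_category_model
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$cohort, " / ", x$sex, " (n = ", x$n, ")\n", sep = "")
  cat("  BMI category proportions:",
      paste(sprintf("%s: %.3f", bmi_category_labels, x$proportions),
            collapse = ", "), "\n")
  invisible(x)
}

draw_within_category <- function(rule, n) {
  switch(rule$type,
    uniform = {
      if (!(rule$max > rule$min)) stop("degenerate uniform support for BMI category")
      stats::runif(n, rule$min, rule$max)
    },
    shifted_exponential = {
      if (!(rule$mean > 0)) stop("degenerate exponential mean for BMI category")
      rule$shift + stats::rexp(n, rate = 1 / rule$mean)
    },
    stop("unknown within-category distribution type: ", rule$type)
  )
}

#' Draw a synthetic reference-cohort BMI sample
#'
#' Draws BMI values whose category frequencies follow the cohort's published
#' proportions, with the within-category shape supplied by the spec, and
#' attaches age/weight/height covariates via [attach_covariates()]. This is a
#' synthetic stand-in for a cohort's observed BMI microdata, which is not
#' published.
#'
#' @param spec A [cohort_spec()].
#' @param size Number of records to draw; defaults to the cohort's published n.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return A tibble with columns `bmi`, `age`, `weight`, `height` and
#'   attributes `spec` and `seed`.
#' @export
#' @examples
#' ref <- sample_reference_bmi(cohort_spec("GTEx", "women"), seed = 1)
#' category_proportions(ref$bmi)
sample_reference_bmi <- function(spec, size = spec$n, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), size >= 1)
  for (k in which(spec$proportions > 0)) {
    rule <- spec$within_category_model[[k]]
    if (identical(rule$type, "uniform") && !(rule$max > rule$min)) {
      stop("category ", k, " has positive proportion but degenerate uniform support")
    }
    if (identical(rule$type, "shifted_exponential") && !(rule$mean > 0)) {
      stop("category ", k, " has positive proportion but degenerate exponential mean")
    }
  }
  draw <- function() {
    cat_idx <- sample.int(4L, size, replace = TRUE, prob = spec$proportions)
    bmi <- numeric(size)
    for (k in seq_len(4L)) {
      sel <- cat_idx == k
      if (any(sel)) {
        bmi[sel] <- draw_within_category(spec$within_category_model[[k]], sum(sel))
      }
    }
    cov <- attach_covariates(bmi)
    tibble::tibble(bmi = bmi, age = cov$age, weight = cov$weight,
                   height = cov$height)
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  attr(out, "spec") <- spec
  attr(out, "seed") <- seed
  out
}

#' Attach age, weight and height covariates to BMI values
#'
#' Height is drawn independently of BMI from a truncated normal (mean 1.65 m,
#' sd 0.08 m, truncated to \[1.40, 2.05\]); weight is then defined exactly as
#' `bmi * height^2`; age is uniform on \[21, 70\]. The resulting linear
#' predictability of BMI from (age, weight) is deliberately good but imperfect
#' (R^2 around 0.85 under the defaults), which is what drives the error in
#' estimated inverse-probability weights.
#'
#' @param bmi Positive numeric vector of BMI values (kg/m^2).
#' @param seed Optional integer seed (RNG-state preserving, as in
#'   [sample_reference_bmi()]).
#' @param height_mean,height_sd,height_range Height distribution controls
#'   (metres).
#' @param age_range Uniform age range (years).
#' @return A tibble with columns `age`, `weight`, `height`.
#' @export
attach_covariates <- function(bmi, seed = NULL,
                              height_mean = 1.65, height_sd = 0.08,
                              height_range = c(1.40, 2.05),
                              age_range = c(21, 70)) {
  if (any(bmi <= 0)) stop("all BMI values must be positive")
  n <- length(bmi)
  draw <- function() {
    height <- stats::rnorm(n, height_mean, height_sd)
    # redraw out-of-range heights: truncation, not clamping, keeps the shape
    bad <- which(height < height_range[1] | height > height_range[2])
    while (length(bad) > 0) {
      height[bad] <- stats::rnorm(length(bad), height_mean, height_sd)
      bad <- bad[height[bad] < height_range[1] | height[bad] > height_range[2]]
    }
    age <- stats::runif(n, age_range[1], age_range[2])
    tibble::tibble(age = age, weight = bmi * height^2, height = height)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Empirical BMI category proportions
#'
#' Fractions of records falling in \[0, 18.5), \[18.5, 25), \[25, 30) and
#' \[30, Inf) kg/m^2 (left-closed bins: 18.5 counts as normal weight).
#'
#' @param bmi Non-empty numeric vector of BMI values.
#' @return Named numeric 4-vector summing to 1.
#' @export
#' @examples
#' category_proportions(c(17, 22, 27, 33))
category_proportions <- function(bmi) {
  if (length(bmi) == 0) stop("empty BMI vector")
  idx <- findInterval(bmi, bmi_category_breaks) + 1L
  p <- tabulate(idx, nbins = 4L) / length(bmi)
  stats::setNames(p, bmi_category_labels)
}
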