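#' Bind replicate tables from several scenario results
#'
#' @param ... `scenario_result` objects (or a single list of them).
#' @return A tibble of all replicate rows with `scenario` and `ipw` label
#'   columns prepended.
#' @export
bind_scenarios <- function(...) {
  results <- list(...)
  if (length(results) == 1 && !inherits(results[[1]], "scenario_result")) {
    results <- results[[1]]
  }
  purrr::map_dfr(results, function(res) {
    stopifnot(inherits(res, "scenario_result"))
    dplyr::mutate(res$replicates,
                  scenario = res$config$scenario, ipw = res$config$ipw,
                  .before = 1)
  })
}

scenario_label <- function(tab) {
  factor(ifelse(tab$ipw == "none", tab$scenario,
                paste0(tab$scenario, " + IPW (", tab$ipw, ")")))
}

#' Distribution of stage-2 relative bias across scenarios
#'
#' Boxplots of the per-replicate relative bias of the expression-trait
#' association estimate, one box per scenario/IPW combination, with a dashed
#' line at zero bias.
#'
#' @param ... `scenario_result` objects (or one list of them).
#' @return A ggplot object.
#' @export
plot_relative_bias <- function(...) {
  tab <- bind_scenarios(...)
  tab$label <- scenario_label(tab)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$label, y = .data$rel_bias_gamma1,
                                    fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.2, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Relative bias of gamma1 estimate (%)") +
    ggplot2::theme_minimal()
}

#' Distribution of mean predicted expression across scenarios
#'
#' Densities of the per-replicate mean predicted expression in the GWAS
#' sample (log2 scale); biased stage-1 fits shift this distribution downward
#' and shrink its spread relative to random sampling.
#'
#' @param ... `scenario_result` objects (or one list of them).
#' @param population_mean Optional population mean expression to mark with a
#'   dotted vertical line.
#' @return A ggplot object.
#' @export
plot_predicted_expression <- function(..., population_mean = NULL) {
  tab <- bind_scenarios(...)
  tab$label <- scenario_label(tab)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$xhat_mean,
                                         colour = .data$label)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "Mean predicted expression (log2 units)", y = "Density",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(population_mean)) {
    p <- p + ggplot2::geom_vline(xintercept = population_mean,
                                 linetype = "dotted")
  }
  p
}

#' Stage-1 coefficient relative bias across scenarios
#'
#' Boxplots of the per-replicate relative bias of the stage-1 intercept and
#' SNP coefficients, faceted by coefficient.
#'
#' @param ... `scenario_result` objects (or one list of them).
#' @return A ggplot object.
#' @export
plot_stage1_bias <- function(...) {
  tab <- bind_scenarios(...)
  tab$label <- scenario_label(tab)
  long <- tidyr::pivot_longer(
    tab, dplyr::all_of(c("rel_bias_alpha0", "rel_bias_alpha1",
                         "rel_bias_alpha2")),
    names_to = "coefficient", names_prefix = "rel_bias_",
    values_to = "rel_bias"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$rel_bias,
                                     fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.2, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~coefficient, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Relative bias (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of stage-2 relative bias for one scenario
#' @param object A `scenario_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scenario_result <- function(object, ...) {
  ggplot2::ggplot(object$replicates,
                  ggplot2::aes(x = .data$rel_bias_gamma1)) +
    ggplot2::geom_histogram(bins = 50, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      title = paste0(object$config$scenario,
                     if (object$config$ipw != "none")
                       paste0(" + IPW (", object$config$ipw, ")") else ""),
      x = "Relative bias of gamma1 estimate (%)", y = "Replicates"
    ) +
    ggplot2::theme_minimal()
}
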