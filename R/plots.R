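#' Plot module completeness over time
#'
#' One line per module: mean completeness across replicates, with a ribbon
#' spanning +/- 1 sd.
#'
#' @param completeness A [module_completeness()] tibble.
#' @return A ggplot object.
#' @export
plot_module_completeness <- function(completeness) {
  summ <- completeness |>
    dplyr::group_by(.data$timepoint, .data$module) |>
    dplyr::summarise(mean = mean(.data$completeness),
                     sd = stats::sd(.data$completeness), .groups = "drop") |>
    dplyr::mutate(module = factor(.data$module))
  ggplot2::ggplot(summ, ggplot2::aes(.data$timepoint, .data$mean,
                                     colour = .data$module, fill = .data$module)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, .data$mean - .data$sd),
                                      ymax = pmin(1, .data$mean + .data$sd)),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "timepoint", y = "module completeness",
                  colour = "module", fill = "module") +
    ggplot2::theme_minimal()
}

#' @rdname extract_timepoint_networks
#' @param object A `timepoint_networks` tibble.
#' @param ... Unused.
#' @method autoplot timepoint_networks
#' @export
autoplot.timepoint_networks <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(dplyr::all_of(c("modularity", "clustering",
                                        "coexclusion_proportion")),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$timepoint, .data$value)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "steelblue", na.rm = TRUE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "timepoint", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname ses_dispersion
#' @param object A `dispersion_result` tibble.
#' @method autoplot dispersion_result
#' @export
autoplot.dispersion_result <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(dplyr::all_of(c("nri", "nti")),
                        names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$timepoint, .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "firebrick", na.rm = TRUE) +
    ggplot2::facet_wrap(~index, labeller = ggplot2::labeller(index = toupper)) +
    ggplot2::labs(x = "timepoint", y = "standardized effect size (negated)") +
    ggplot2::theme_minimal()
}

#' Plot alpha-diversity indices over time
#'
#' @param alpha An [alpha_diversity()] tibble.
#' @return A ggplot object.
#' @export
plot_alpha_diversity <- function(alpha) {
  long <- tidyr::pivot_longer(alpha,
                              dplyr::any_of(c("q0", "q1", "q2", "pd0")),
                              names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$timepoint, .data$value)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "darkgreen", na.rm = TRUE) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "timepoint", y = "effective number of taxa") +
    ggplot2::theme_minimal()
}
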