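# ggplot2 visualisations for the main result types.

#' Kaplan-Meier curves of a two-group survival comparison
#'
#' Step curves of bone-metastasis-free survival per predicted risk group,
#' annotated with the log-rank p-value.
#'
#' @param object A `survival_comparison` from [km_logrank()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.survival_comparison <- function(object, ...) {
  curves <- dplyr::bind_rows(
    dplyr::distinct(object$curves, .data$group) %>%
      dplyr::mutate(time = 0, surv = 1, n_risk = NA_integer_,
                    n_event = NA_integer_),
    object$curves
  )
  ggplot2::ggplot(curves, ggplot2::aes(.data$time, .data$surv,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Time (years)", y = "Metastasis-free survival",
      colour = "Predicted group",
      subtitle = sprintf("log-rank p = %.3g", object$logrank_p)
    ) +
    ggplot2::theme_minimal()
}

#' Degree-distribution diagnostics of a dependency network
#'
#' log10-log10 scatter of degree versus frequency for in- and out-degree,
#' the conventional visual check that the network is scale-free.
#'
#' @param object A `dependency_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dependency_network <- function(object, ...) {
  edges <- object$edges
  nodes <- object$nodes
  deg <- dplyr::bind_rows(
    tibble::tibble(direction = "in",
                   degree = as.numeric(table(factor(edges$dependent,
                                                    levels = nodes)))),
    tibble::tibble(direction = "out",
                   degree = as.numeric(table(factor(edges$modulator,
                                                    levels = nodes))))
  ) %>%
    dplyr::filter(.data$degree > 0) %>%
    dplyr::count(.data$direction, .data$degree)
  ggplot2::ggplot(deg, ggplot2::aes(.data$degree, .data$n)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~direction) +
    ggplot2::labs(x = "Degree", y = "Number of genes") +
    ggplot2::theme_minimal()
}

#' Driver-frequency profile across randomized matching runs
#'
#' Bar heights count, for each driver frequency, how many genes reached it;
#' the genes at the right edge (frequency = runs) are the all-run driver
#' candidates passed on to signature selection.
#'
#' @param freq A `driver_freq` table from [sample_driver_sets()].
#' @return A ggplot.
#' @export
plot_driver_frequency <- function(freq) {
  runs <- attr(freq, "runs")
  d <- dplyr::count(tibble::as_tibble(freq), .data$count)
  ggplot2::ggplot(d, ggplot2::aes(.data$count, .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = sprintf("Driver frequency (of %d runs)", runs),
                  y = "Number of genes") +
    ggplot2::theme_minimal()
}
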