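#' Plot per-region mixing scores
#'
#' Bar plot of the mixing score by region — the figure used to compare
#' penalty settings (lower bars mean the regional signal is better mixed
#' across clusters).
#'
#' @param object A `starmaps_mixing` tibble from [mixing_score()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.starmaps_mixing <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$region, y = .data$score)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "mixing score",
                  title = paste0("Region mixing across ",
                                 attr(object, "n_clusters"), " clusters")) +
    ggplot2::theme_minimal()
}

#' Plot the objective trace of a fit
#'
#' @param object A `starmaps_fit`.
#' @param ... Unused.
#' @return A ggplot object (objective vs outer iteration, log10 y).
#' @export
autoplot.starmaps_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$objective_trace) - 1L,
                       objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "objective") +
    ggplot2::theme_minimal()
}

#' Plot batch and region perturbation magnitudes
#'
#' @param object A `starmaps_perturbation` tibble from
#'   [perturbation_magnitudes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.starmaps_perturbation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$label, y = .data$distance,
                                       fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~type, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "subspace distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot the percentage of enriched cells per region
#'
#' @param object A `starmaps_region_summary` from
#'   [region_enrichment_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.starmaps_region_summary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$region,
                                                  .data$pct_enriched),
                               y = .data$pct_enriched)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% cells in enriched units") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
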