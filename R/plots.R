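#' Plot a projection's annual burden trajectories
#'
#' @param object A `cvd_projection`.
#' @param metrics Annual columns to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cvd_projection <- function(object,
                                    metrics = c("cvd_deaths", "new_cases"),
                                    ...) {
  object$annual |>
    dplyr::select("year", dplyr::all_of(metrics)) |>
    tidyr::pivot_longer(-"year", names_to = "metric") |>
    ggplot2::ggplot(ggplot2::aes(.data$year, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s — %s scenario", object$country_id,
                                  object$scenario)) +
    ggplot2::theme_minimal()
}

#' Compare scenarios within a resultset
#'
#' @param object A `cvd_resultset`.
#' @param metric Annual column to compare across scenarios.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cvd_resultset <- function(object, metric = "cvd_deaths", ...) {
  object$annual |>
    dplyr::group_by(.data$scenario, .data$interventions, .data$year) |>
    dplyr::summarise(value = sum(.data[[metric]]), .groups = "drop") |>
    ggplot2::ggplot(ggplot2::aes(.data$year, .data$value,
                                 colour = .data$scenario,
                                 linetype = .data$interventions)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Plot a cohort health-state trajectory
#'
#' Stacked-area view of the four mutually exclusive cohort states over time.
#'
#' @param trajectory Output of [cohort_health_trajectory()].
#' @return A ggplot object.
#' @export
plot_cohort_health <- function(trajectory) {
  trajectory |>
    tidyr::pivot_longer(c("free", "hypertensive", "cvd", "dead"),
                        names_to = "state", values_to = "probability") |>
    dplyr::mutate(state = factor(.data$state,
                                 c("dead", "cvd", "hypertensive", "free"))) |>
    ggplot2::ggplot(ggplot2::aes(.data$year, .data$probability,
                                 fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = NULL, y = "probability") +
    ggplot2::theme_minimal()
}

#' Plot a demographic decomposition
#'
#' @param decomposition Output of [decompose_change()] or
#'   [decompose_projection()].
#' @return A ggplot object.
#' @export
plot_decomposition <- function(decomposition) {
  bars <- dplyr::filter(decomposition, .data$component != "total")
  total <- dplyr::filter(decomposition, .data$component == "total")
  ggplot2::ggplot(bars, ggplot2::aes(.data$component, .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = total$percent, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "% change in new cases") +
    ggplot2::theme_minimal()
}
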