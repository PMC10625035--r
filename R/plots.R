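#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot cumulative cost curves
#'
#' Mean cumulative cost per year by clinical course, with a +/- 1 SD
#' ribbon.
#'
#' @param object A [build_cost_curves()] result.
#' @param stream `"direct"` or `"indirect"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cost_curves
#' @export
autoplot.cost_curves <- function(object, stream = c("direct", "indirect"),
                                 ...) {
  stream <- match.arg(stream)
  m <- paste0(stream, "_mean")
  s <- paste0(stream, "_sd")
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data[[m]],
                                   colour = .data$group,
                                   fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, .data[[m]] - .data[[s]]),
                                      ymax = .data[[m]] + .data[[s]]),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("$%.0fk", x / 1000)) +
    ggplot2::labs(x = "Years since implantation",
                  y = sprintf("Cumulative %s cost (2018 USD)", stream),
                  colour = "Clinical course", fill = "Clinical course") +
    ggplot2::theme_minimal()
}

#' Plot the PSA cost distribution
#'
#' Histogram of the expected 20-year cost across parameter draws, one
#' panel per cost stream.
#'
#' @param object A [run_psa()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psa_result
#' @export
autoplot.psa_result <- function(object, ...) {
  df <- object$draws |>
    dplyr::select("direct", "indirect") |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "stream",
                        values_to = "cost")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cost)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue", colour = NA) +
    ggplot2::facet_wrap(~stream, scales = "free") +
    ggplot2::labs(x = "Expected 20-year cost per patient (2018 USD)",
                  y = "Draws") +
    ggplot2::theme_minimal()
}

#' Plot simulated per-patient cost totals
#'
#' @param object A [simulate_cohort()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cohort_summary
#' @export
autoplot.cohort_summary <- function(object, ...) {
  df <- object$patients |>
    tidyr::pivot_longer(c("direct", "indirect"), names_to = "stream",
                        values_to = "cost")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cost)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey30", colour = NA) +
    ggplot2::facet_wrap(~stream, scales = "free") +
    ggplot2::labs(x = "Discounted 20-year cost per patient (2018 USD)",
                  y = "Patients") +
    ggplot2::theme_minimal()
}

#' Plot surgical-volume trends
#'
#' Yearly surgery counts by age group, postoperative pacemaker
#' implantations, and roster size, on a log scale.
#'
#' @param volumes A volume table (see [generate_volume_series()]).
#' @return A ggplot object.
#' @export
plot_volume_trends <- function(volumes) {
  df <- volumes |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(-"year", names_to = "series", values_to = "count") |>
    dplyr::filter(.data$count > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$count,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Year", y = "Count (log scale)", colour = NULL) +
    ggplot2::theme_minimal()
}
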