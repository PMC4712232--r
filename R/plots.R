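#' Plot an activation map (anterior view)
#'
#' Scatter of heart nodes in the anterior projection (x lateral, z cranial)
#' coloured by activation time — a flat rendering of the isochrones.
#'
#' @param object An [activation_map()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.activation_map <- function(object, ...) {
  d <- tibble::tibble(x = object$positions[, 1], z = object$positions[, 3],
                      t = object$times, anterior = object$positions[, 2] >=
                        median(object$positions[, 2]))
  ggplot2::ggplot(dplyr::filter(d, .data$anterior),
                  ggplot2::aes(.data$x, .data$z, colour = .data$t)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c(name = "activation (ms)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "z (mm)",
                  title = "Activation isochrones, anterior view") +
    ggplot2::theme_minimal()
}

#' Plot the 16-point anterior correlation profile
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  d <- dplyr::mutate(object$sample_points, point = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(.data$point, .data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = "anterior sampling point", y = "Pearson R",
                  title = "Correlation at anterior epicardial points") +
    ggplot2::theme_minimal()
}

#' Plot a study result
#'
#' Configuration studies show mean +/- sd of the overall source correlation
#' per electrode layout; pacing studies show the distribution of
#' localization errors and point-spread cross-sections.
#'
#' @param object A `study_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_result <- function(object, ...) {
  if (object$kind == "configuration") {
    d <- dplyr::mutate(object$summary,
                       layout = factor(.data$layout, levels = .data$layout))
    ggplot2::ggplot(d, ggplot2::aes(.data$layout, .data$mean_r)) +
      ggplot2::geom_pointrange(ggplot2::aes(
        ymin = .data$mean_r - .data$sd_r, ymax = .data$mean_r + .data$sd_r)) +
      ggplot2::labs(x = NULL, y = "overall Pearson R",
                    title = "Source correlation by electrode configuration") +
      ggplot2::theme_minimal()
  } else {
    d <- tidyr::pivot_longer(object$cells,
                             c("localization_error_mm", "point_spread_mm"),
                             names_to = "metric", values_to = "mm")
    ggplot2::ggplot(d, ggplot2::aes(.data$site, .data$mm)) +
      ggplot2::geom_boxplot() +
      ggplot2::facet_wrap(~metric, scales = "free_y") +
      ggplot2::labs(x = "pacing site", y = "mm",
                    title = "Pacing localization and point spread") +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
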