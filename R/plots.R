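#' Centile chart of a normative run
#'
#' Growth-chart style figure: the seven centile curves of the fitted
#' normative distribution against age, with training subjects drawn as open
#' circles and test subjects as filled dots.
#'
#' @param x A `normative_run`.
#' @param region Region to plot; default the first modeled region.
#' @return A ggplot object.
#' @export
plot_centiles <- function(x, region = NULL) {
  stopifnot(inherits(x, "normative_run"))
  region <- region %||% names(x$models)[1]
  cc <- dplyr::filter(x$centiles, .data$region == !!region)
  dv <- dplyr::filter(x$deviations, .data$region == !!region)
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = cc,
      ggplot2::aes(x = .data$age, y = .data$value,
                   group = factor(.data$quantile)),
      colour = "grey40", linewidth = 0.4
    ) +
    ggplot2::geom_point(
      data = dv,
      ggplot2::aes(x = .data$age, y = .data$y, colour = .data$half,
                   shape = .data$half),
      size = 1.8
    ) +
    ggplot2::scale_colour_manual(values = c(train = "#3366BB",
                                            test = "#CC3333")) +
    ggplot2::scale_shape_manual(values = c(train = 1, test = 16)) +
    ggplot2::labs(x = "Age (years)", y = "Normalized uptake",
                  title = region) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.normative_run <- function(object, region = NULL, ...) {
  plot_centiles(object, region = region)
}

#' Deviation-score plot
#'
#' Per-subject Z-scores against age with the +/-2 extreme-deviation bounds.
#'
#' @param x A `normative_run`.
#' @param region Region to plot; default the first modeled region.
#' @return A ggplot object.
#' @export
plot_deviations <- function(x, region = NULL) {
  stopifnot(inherits(x, "normative_run"))
  region <- region %||% names(x$models)[1]
  dv <- dplyr::filter(x$deviations, .data$region == !!region)
  ggplot2::ggplot(dv, ggplot2::aes(x = .data$age, y = .data$z,
                                   colour = .data$extreme)) +
    ggplot2::geom_hline(yintercept = c(-2, 2), linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::scale_colour_manual(values = c(none = "grey30",
                                            positive = "#CC3333",
                                            negative = "#3366BB")) +
    ggplot2::labs(x = "Age (years)", y = "Deviation Z-score",
                  title = region) +
    ggplot2::theme_minimal()
}
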