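#' Plot NPQ induction curves
#'
#' One line per disc, coloured by accession, faceted by treatment, with the
#' light window shaded. Works on the output of [compute_npq()] or
#' [compute_npq_a()].
#'
#' @param data NPQ table with `time_min`, the value column, `disc_id`, and
#'   (optionally) `accession` / `treatment`.
#' @param value Column to plot, `"npq"` (default) or `"npq_a"`.
#' @param protocol A [flash_protocol()] for the light-window shading.
#' @return A ggplot object.
#' @export
plot_npq_curves <- function(data, value = "npq",
                            protocol = protocol_preset("cf_imager")) {
  colour <- if ("accession" %in% names(data)) "accession" else NULL
  p <- ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data$time_min, y = .data[[value]],
                 group = .data$disc_id)
  ) +
    ggplot2::annotate("rect",
                      xmin = protocol$light_on_min,
                      xmax = protocol$light_off_min,
                      ymin = -Inf, ymax = Inf,
                      fill = "gold", alpha = 0.15) +
    ggplot2::geom_line(
      if (!is.null(colour)) ggplot2::aes(colour = .data$accession),
      alpha = 0.6
    ) +
    ggplot2::geom_point(
      if (!is.null(colour)) ggplot2::aes(colour = .data$accession),
      size = 1
    ) +
    ggplot2::labs(x = "Time after light-on (min)",
                  y = if (value == "npq_a") "Adjusted NPQ" else "NPQ") +
    ggplot2::theme_minimal()
  if ("treatment" %in% names(data)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$treatment))
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.hyperbolic_fit <- function(object, ...) {
  d <- object$data
  tt <- seq(0, max(d$time_min), length.out = 200)
  curve <- tibble::tibble(
    time_min = tt,
    value = object$amplitude * tt / (tt + object$half_time)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(
      x = "Time after light-on (min)", y = object$curve_type,
      subtitle = sprintf("A = %.3g, K = %.3g min, A/K = %.3g min^-1",
                         object$amplitude, object$half_time,
                         object$initial_slope)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a binned reflectance spectrum
#'
#' @param spectrum Output of [bin_spectrum()].
#' @param highlight_bands Wavelengths to mark (defaults to the index bands).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum,
                          highlight_bands = c(510, 531, 550, 570, 700, 800)) {
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(x = .data$wavelength_nm,
                               y = .data$reflectance)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = highlight_bands, linetype = "dotted",
                        colour = "grey50") +
    ggplot2::labs(x = "Wavelength (nm)", y = "Reflectance") +
    ggplot2::theme_minimal()
}
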