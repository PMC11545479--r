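#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.heightmap <- function(object, ...) {
  px_um <- pixel_size(object) / 1000
  df <- tidyr::expand_grid(row = seq_len(nrow(object)),
                           col = seq_len(ncol(object))) |>
    dplyr::mutate(x = (.data$col - 0.5) * px_um,
                  y = (nrow(object) - .data$row + 0.5) * px_um,
                  height = as.vector(unclass(object)[cbind(.data$row, .data$col)]))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$height)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "height (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = map_name(object)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.radial_psd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$spatial_frequency, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "spatial frequency (1/nm)",
                  y = expression(PSD ~ (nm^2 %.% nm)),
                  title = "radially averaged power spectrum") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hertz_fit <- function(object, ...) {
  geom <- (4 / 3) * sqrt(object$probe$radius) /
    (1 - object$probe$poisson_ratio^2)
  df <- object$data |>
    dplyr::mutate(fitted = object$E * 1e-6 * geom * .data$indentation^1.5)
  ggplot2::ggplot(df, ggplot2::aes(.data$indentation, .data$force)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "indentation (nm)", y = "force (nN)",
                  title = sprintf("Hertz fit: E = %.2f kPa", object$E)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hb_fit <- function(object, ...) {
  df <- object$data |>
    tidyr::pivot_longer(c("od", "fitted"), names_to = "series",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(od = "grey30",
                                            fitted = "firebrick")) +
    ggplot2::labs(x = "wavelength (nm)", y = "optical density",
                  title = "hemoglobin spectral unmixing") +
    ggplot2::theme_minimal()
}

#' Composition bar chart of a classified scene
#'
#' @param x A `scene_composition` from [scene_composition()].
#' @return A ggplot object.
#' @export
plot_composition <- function(x) {
  ggplot2::ggplot(x$composition,
                  ggplot2::aes(.data$label, .data$percent, fill = .data$label)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "% of classified cells") +
    ggplot2::theme_minimal()
}
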