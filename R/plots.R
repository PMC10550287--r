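#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heat map of an intensity image
#'
#' @param object An [intensity_image()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.intensity_image <- function(object, ...) {
  as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$x_um, .data$y_um,
                                 fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  fill = object$channel) +
    ggplot2::theme_minimal()
}

#' Traction magnitude map with direction glyphs
#'
#' @param object A [traction_field()].
#' @param arrow_every Draw an arrow at every n-th node, default 8.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.traction_field <- function(object, arrow_every = 8, ...) {
  df <- as_tibble(object) |>
    dplyr::mutate(magnitude = sqrt(.data$tx_pa^2 + .data$ty_pa^2))
  h <- field_spacing_um(object)
  arrows <- df |>
    dplyr::filter(
      (round(.data$x_um / h - 0.5) %% arrow_every) == 0,
      (round(.data$y_um / h - 0.5) %% arrow_every) == 0,
      .data$magnitude > 0
    )
  sc <- 2 * h / max(df$magnitude)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$magnitude)) +
    ggplot2::geom_segment(
      data = arrows,
      ggplot2::aes(xend = .data$x_um + sc * .data$tx_pa,
                   yend = .data$y_um + sc * .data$ty_pa),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
      linewidth = 0.3, colour = "white"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = "|T| (Pa)") +
    ggplot2::theme_minimal()
}

#' Displacement magnitude map
#'
#' @param object A [displacement_field()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.displacement_field <- function(object, ...) {
  as_tibble(object) |>
    dplyr::mutate(magnitude = sqrt(.data$ux_um^2 + .data$uy_um^2)) |>
    ggplot2::ggplot(ggplot2::aes(.data$x_um, .data$y_um,
                                 fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = "|u| (µm)") +
    ggplot2::theme_minimal()
}

#' Wind-rose plot of migration directions
#'
#' @param tracks Track tibble (`track_id`, `t_min`, `x_um`, `y_um`).
#' @param n_sectors Number of angular sectors.
#' @return A ggplot (polar bar chart of net-displacement angles).
#' @export
plot_windrose <- function(tracks, n_sectors = 16) {
  wr <- windrose(tracks, n_sectors)
  width_deg <- 360 / n_sectors
  wr$sectors |>
    dplyr::mutate(theta_mid_deg = .data$theta_start_rad * 180 / pi +
                    width_deg / 2) |>
    ggplot2::ggplot(ggplot2::aes(.data$theta_mid_deg, .data$count)) +
    ggplot2::geom_col(width = width_deg, fill = "steelblue",
                      colour = "grey20", linewidth = 0.2) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = NULL, y = "tracks") +
    ggplot2::theme_minimal()
}

#' Force curve with fitted Hertz model overlay
#'
#' @param object A `hertz_fit`.
#' @param ... Unused.
#' @return A ggplot of force vs indentation with the fitted curve.
#' @export
autoplot.hertz_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(delta_um = seq(0, max(d$delta_um), length.out = 200))
  grid$force_n <- hertz_force(object$modulus_pa, object$tip_radius_um,
                              grid$delta_um, object$poisson_ratio)
  ggplot2::ggplot(d, ggplot2::aes(.data$delta_um, .data$force_n * 1e9)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "indentation (µm)", y = "force (nN)",
                  title = sprintf("E = %.0f Pa", object$modulus_pa)) +
    ggplot2::theme_minimal()
}
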