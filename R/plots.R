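#' Plot a simulation snapshot
#'
#' Cell positions coloured by phase, vessel sites and the resection cavity
#' outline.
#'
#' @param st A `sim_state`.
#' @return A ggplot object.
#' @export
plot_cells <- function(st) {
  cells <- dplyr::mutate(st$cells,
                         x_mm = .data$x / 1000, y_mm = .data$y / 1000,
                         state = ifelse(.data$status == "apoptotic",
                                        "apoptotic", .data$phase))
  vs <- tibble::as_tibble(st$vessels$sites, .name_repair = ~c("x_mm", "y_mm"))
  th <- seq(0, 2 * pi, length.out = 120)
  cav <- tibble::tibble(
    x_mm = st$cavity$center[1] + st$cavity$radius * cos(th),
    y_mm = st$cavity$center[2] + st$cavity$radius * sin(th))
  ggplot2::ggplot(cells, ggplot2::aes(.data$x_mm, .data$y_mm)) +
    ggplot2::geom_path(data = cav, colour = "black", linetype = "dashed") +
    ggplot2::geom_point(data = vs, shape = 3, colour = "grey40", size = 2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$state), size = 1) +
    ggplot2::scale_colour_manual(values = c(
      Tm = "red", Tp = "blue", neither = "grey60", apoptotic = "darkgreen")) +
    ggplot2::coord_fixed(xlim = c(0, st$config$L), ylim = c(0, st$config$L)) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = NULL,
                  title = sprintf("t = %g h", st$t)) +
    ggplot2::theme_minimal()
}

#' Plot a concentration field
#'
#' @param st A `sim_state` (or a `field_state` plus `L`).
#' @param field One of `"K"`, `"G"`, `"C"`, `"rho"`, `"P"`, `"D"`.
#' @return A ggplot object.
#' @export
plot_field <- function(st, field = "G") {
  fs <- if (inherits(st, "sim_state")) st$fields else st
  df <- expand.grid(x_mm = fs$xs, y_mm = fs$ys)
  df$value <- as.numeric(fs[[field]])
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = field) +
    ggplot2::theme_minimal()
}

#' Plot population time courses of a run
#'
#' @param st A `sim_state`.
#' @return A ggplot object.
#' @export
plot_populations <- function(st) {
  m <- sim_metrics(st) |>
    tidyr::pivot_longer(-"t", names_to = "compartment", values_to = "count")
  ggplot2::ggplot(m, ggplot2::aes(.data$t, .data$count,
                                  colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "cells", colour = NULL) +
    ggplot2::theme_minimal()
}
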