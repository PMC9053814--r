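#' Plot-of-origin view of one or more trajectories
#'
#' Every trajectory is translated so its first point sits at the origin (the
#' standard plot-of-origin visualization for migration data), then drawn as a
#' path coloured by cell.
#'
#' @param trajs A `bleb_trajectory` or a list of them.
#' @return A ggplot object.
#' @export
plot_origin <- function(trajs) {
  if (inherits(trajs, "bleb_trajectory")) trajs <- list(trajs)
  tb <- bind_rows(lapply(trajs, zero_origin))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                   colour = .data$cell_id)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (\u00b5m)", y = "y (\u00b5m)", colour = NULL,
                  title = "Plot of origin") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bleb_trajectory <- function(object, ...) plot_origin(object)

#' Bleb area over time, one line per track
#'
#' @param object A `bleb_tracks` tibble from [track_blebs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bleb_tracks <- function(object, ...) {
  dt <- attr(object, "frame_interval_min") %||% 8
  tb <- mutate(as_tibble(object), t_min = .data$frame * dt)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$t_min, y = .data$area_um2,
                                   group = .data$track_id,
                                   colour = factor(.data$track_id))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (min)", y = "bleb area (\u00b5m\u00b2)",
                  colour = "track") +
    ggplot2::theme_minimal()
}

#' Overview panel for an analyzed cell
#'
#' Compartment areas over time (top) and the zero-origin trajectory path
#' (speeds are in the `speeds` element of the object).
#'
#' @param object A `bleb_cell` from [analyze_cell()].
#' @param ... Unused.
#' @return A ggplot object (compartment areas over time).
#' @export
autoplot.bleb_cell <- function(object, ...) {
  tb <- filter(object$frames,
               .data$compartment %in% c("whole_cell", "cell_body",
                                        "all_blebs", "largest_bleb"))
  dt <- object$masks$whole_cell$frame_interval_min
  tb <- mutate(tb, t_min = .data$frame * dt)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$t_min, y = .data$area_um2,
                                   colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (min)", y = "area (\u00b5m\u00b2)", colour = NULL,
      title = paste0(object$cell_id, " \u2014 ", object$phenotype$label)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
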