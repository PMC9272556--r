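#' Plot the cells of one imaged field
#'
#' Point map of a field's cells in micrometer coordinates (y downward, the
#' image convention), colored by class or by a phenotype assignment.
#'
#' @param cells A validated cell tibble.
#' @param roi `roi_id` of the field to plot (default: the first).
#' @param color_by Column to color by (default `cell_class`).
#' @return A ggplot object.
#' @export
plot_roi <- function(cells, roi = NULL, color_by = "cell_class") {
  if (is.null(roi)) roi <- cells$roi_id[1]
  d <- cells %>% filter(.data$roi_id == !!roi)
  ggplot2::ggplot(d, ggplot2::aes(.data$x_um, .data$y_um,
                                  color = .data[[color_by]])) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = roi, x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a tumor-immune neighbor graph
#'
#' Central cells, peripheral cells, and the pairing edges within the radius.
#'
#' @param object An `si_graph`.
#' @param central,peripheral The cell tibbles the graph was built from
#'   (needed for coordinates).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot si_graph
#' @export
autoplot.si_graph <- function(object, central, peripheral, ...) {
  pts <- bind_rows(
    central %>% mutate(role = "central (tumor)"),
    peripheral %>% mutate(role = "peripheral (immune)")
  )
  seg <- object$edges %>%
    left_join(central %>% select(central_id = "cell_id", x0 = "x_um", y0 = "y_um"),
              by = "central_id") %>%
    left_join(peripheral %>% select(peripheral_id = "cell_id", x1 = "x_um", y1 = "y_um"),
              by = "peripheral_id")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          color = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(.data$x_um, .data$y_um, color = .data$role),
                        size = 1.2) +
    ggplot2::scale_color_manual(values = c("central (tumor)" = "#c0392b",
                                           "peripheral (immune)" = "#27ae60")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  subtitle = sprintf("radius %g µm, %d edges",
                                     object$radius, nrow(object$edges))) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier step plot
#'
#' @param curves Either an `si_km` object or the `curves` tibble from
#'   [survival_report()] (columns `endpoint`, `group`, `time`, `survival`).
#' @return A ggplot object.
#' @export
plot_km <- function(curves) {
  if (inherits(curves, "si_km")) {
    curves <- tidy(curves) %>% mutate(group = curves$group %||% "all",
                                      endpoint = "survival")
  }
  start <- curves %>%
    distinct(.data$endpoint, .data$group) %>%
    mutate(time = 0, survival = 1)
  d <- bind_rows(start, curves %>% select("endpoint", "group", "time", "survival")) %>%
    arrange(.data$endpoint, .data$group, .data$time)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$survival,
                                       color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "survival probability") +
    ggplot2::theme_minimal()
  if (dplyr::n_distinct(d$endpoint) > 1L) {
    p <- p + ggplot2::facet_wrap(~endpoint)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
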