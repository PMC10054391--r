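#' Visual summaries
#'
#' ggplot2 renderings of the five session summaries: welfare gauges,
#' occupancy heatmap, movement trajectory, nested behavior proportions
#' (doughnut), and the behavior timeline. Each `plot_*()` returns a
#' ggplot object; `autoplot()` methods dispatch on the summary objects.
#'
#' @name plots
NULL

#' @rdname plots
#' @param welfare Welfare-indicator tibble from [welfare_state()].
#' @export
plot_gauges <- function(welfare) {
  df <- dplyr::mutate(welfare,
                      frac = pmin(1, .data$value / (2 * .data$threshold)),
                      label = sprintf("%s\n%.2f / >%g", .data$behavior,
                                      .data$value, .data$threshold))
  ggplot2::ggplot(df) +
    ggplot2::annotate("rect", xmin = 0, xmax = 1, ymin = 0.6, ymax = 1,
                      fill = "grey90") +
    ggplot2::geom_rect(ggplot2::aes(xmin = 0, xmax = .data$frac,
                                    ymin = 0.6, ymax = 1,
                                    fill = .data$flagged)) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(x = 0.5, y = 0.25, label = .data$label),
                       size = 3) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "#2c7fb8",
                                          `TRUE` = "#d7301f"),
                               guide = "none") +
    ggplot2::coord_polar(theta = "x", start = -pi / 2, direction = 1) +
    ggplot2::facet_wrap(~behavior) +
    ggplot2::xlim(0, 2) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Poor-welfare indicators (dashed line = threshold)")
}

#' @rdname plots
#' @param heatmap `pw_heatmap` matrix from [occupancy_heatmap()].
#' @export
plot_heatmap <- function(heatmap) {
  df <- expand.grid(ix = seq_len(nrow(heatmap)), iy = seq_len(ncol(heatmap)))
  df$weight <- as.numeric(heatmap)
  ggplot2::ggplot(df, ggplot2::aes(.data$ix, .data$iy, fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Dog occupancy heatmap", x = NULL, y = NULL,
                  fill = "dwell\n(frames)") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @param traj `pw_trajectory` tibble from [trajectory()].
#' @export
plot_trajectory <- function(traj) {
  p <- ggplot2::ggplot(traj, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(ggplot2::aes(color = .data$color_index)) +
    ggplot2::scale_color_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Movement trajectory", color = "time",
                  x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
  marked <- traj[!is.na(traj$marker), ]
  if (nrow(marked) > 0) {
    p <- p + ggplot2::geom_point(data = marked, shape = 21, size = 4,
                                 stroke = 1.2, fill = "white")
  }
  p
}

#' @rdname plots
#' @param props `pw_proportions` tibble from [proportions()].
#' @export
plot_doughnut <- function(props) {
  props$ring <- ifelse(props$level == "category", 1, 2)
  props <- props[order(props$ring, props$category, props$name), ]
  ggplot2::ggplot(props,
                  ggplot2::aes(x = .data$ring, y = .data$fraction,
                               fill = .data$name)) +
    ggplot2::geom_col(width = 0.9, color = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::xlim(0, 3) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Behavior time budget (outer: behaviors, inner: categories)",
                  fill = NULL)
}

#' @rdname plots
#' @param tl `pw_timeline` tibble from [timeline()].
#' @export
plot_timeline <- function(tl) {
  lanes <- attr(tl, "lanes")
  n_active <- sum(lanes$category == "active")
  ggplot2::ggplot(tl) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start_min, xend = .data$end_min,
                                       y = .data$lane, yend = .data$lane,
                                       color = .data$category),
                          linewidth = 4) +
    ggplot2::geom_hline(yintercept = n_active + 0.5, linetype = "dotted") +
    ggplot2::scale_y_reverse(breaks = lanes$lane, labels = lanes$label) +
    ggplot2::scale_color_manual(values = c(active = "#e6550d",
                                           static = "#3182bd"),
                                limits = c("active", "static")) +
    ggplot2::labs(title = "Behavior timeline", x = "time (min)", y = NULL,
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pw_heatmap <- function(object, ...) plot_heatmap(object)

#' @export
autoplot.pw_trajectory <- function(object, ...) plot_trajectory(object)

#' @export
autoplot.pw_proportions <- function(object, ...) plot_doughnut(object)

#' @export
autoplot.pw_timeline <- function(object, ...) plot_timeline(object)

#' Tidy and glance methods for session summaries
#'
#' `tidy()` on a `pw_summary` returns the episode table; `glance()`
#' returns a one-row overview (episode count, observed minutes, flagged
#' indicator count, alert count).
#'
#' @param x A `pw_summary` from [summarize_session()].
#' @param ... Unused.
#' @export
tidy.pw_summary <- function(x, ...) x$episodes

#' @rdname tidy.pw_summary
#' @export
glance.pw_summary <- function(x, ...) {
  tibble::tibble(
    n_episodes = nrow(x$episodes),
    observed_min = sum(x$episodes$duration_s) / 60,
    n_flagged = sum(x$welfare$flagged),
    n_alerts = nrow(x$alerts)
  )
}

#' @export
print.pw_summary <- function(x, ...) {
  cat("Session summary:", nrow(x$episodes), "episodes,",
      sprintf("%.2f", sum(x$episodes$duration_s) / 60), "min observed,",
      sum(x$welfare$flagged), "welfare indicator(s) flagged\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
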