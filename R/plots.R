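#' Plot a migration radar
#'
#' Rose-style plot of the four directionality dials (forward = toward the
#' olfactory bulb at the top).
#'
#' @param object A `saltmig_radar` from [radar_bin()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot saltmig_radar
#' @export
autoplot.saltmig_radar <- function(object, ...) {
  df <- tibble::tibble(
    dial = factor(object$dial, levels = c("forward", "left", "backward", "right")),
    centre = c(0, 90, 180, 270),
    pct = object$pct
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$centre, y = .data$pct,
                                   fill = .data$dial)) +
    ggplot2::geom_col(width = 90, colour = "grey30", alpha = 0.85) +
    ggplot2::coord_polar(theta = "x", start = pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(-45, 315),
                                breaks = c(0, 90, 180, 270),
                                labels = c("forward (OB)", "left",
                                           "backward", "right")) +
    ggplot2::labs(x = NULL, y = "% of cells", fill = "dial") +
    ggplot2::theme_minimal()
}

#' Strip chart of a per-cell metric by group
#'
#' Jittered per-cell points with the group median marked, the usual display
#' for migration metrics.
#'
#' @param metrics Metrics tibble from [compute_cell_metrics()].
#' @param metric Unquoted metric column.
#' @return A ggplot object.
#' @export
plot_metric <- function(metrics, metric) {
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$group, y = {{ metric }})) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.5, size = 1) +
    ggplot2::stat_summary(fun = median, geom = "crossbar", width = 0.5,
                          linewidth = 0.4, colour = "black") +
    ggplot2::theme_classic() +
    ggplot2::labs(x = NULL)
}

#' Plot a track with detected NK events
#'
#' Path of the nucleus in the x,y plane with supra-threshold NK steps
#' highlighted; a quick visual check of event detection.
#'
#' @param track Nucleus track.
#' @param nk_threshold Strict NK threshold, um.
#' @return A ggplot object.
#' @export
plot_track <- function(track, nk_threshold = 6) {
  steps <- step_displacements(track)
  seg <- tibble::tibble(
    x = track$x_um[-nrow(track)], y = track$y_um[-nrow(track)],
    xend = track$x_um[-1], yend = track$y_um[-1],
    nk = steps$displacement > nk_threshold
  )
  ggplot2::ggplot(seg) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       colour = .data$nk)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick"),
                                 labels = c("pause", "NK step"),
                                 name = NULL) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}
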