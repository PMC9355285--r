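#' Plot an in-silico validation grid
#'
#' Box plots of reading or transmission error against the number of active
#' cages, one panel per phase x frequency, colored by output — the
#' standard presentation of the three-phase validation.
#'
#' @param object An `insilico_validation` tibble.
#' @param metric `"reading"` or `"transmission"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot insilico_validation
#' @export
autoplot.insilico_validation <- function(object,
                                         metric = c("reading", "transmission"),
                                         ...) {
  metric <- match.arg(metric)
  ycol <- if (metric == "reading") "reading_error_pct" else
    "transmission_error_pct"
  ylab <- if (metric == "reading") "Reading error (%)" else
    "Transmission error (%)"
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$active_cages), y = .data[[ycol]],
    fill = .data$output
  )) +
    ggplot2::geom_boxplot(outlier.size = 0.5, linewidth = 0.3) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$frequency_hz),
      cols = ggplot2::vars(.data$phase),
      labeller = ggplot2::labeller(
        frequency_hz = function(x) paste0(x, " Hz"),
        phase = function(x) paste("Phase", x)
      )
    ) +
    ggplot2::labs(x = "Active cages", y = ylab, fill = "Output") +
    ggplot2::theme_bw()
}

#' Plot lick/intake correlation
#'
#' Scatter of total licks against consumed grams per session with a
#' least-squares line, optionally colored by liquid.
#'
#' @param object A `lick_correlation` result from [intake_correlation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lick_correlation
#' @export
autoplot.lick_correlation <- function(object, ...) {
  data <- attr(object, "data")
  aes <- if ("liquid" %in% names(data)) {
    ggplot2::aes(x = .data$intake_g, y = .data$total_licks,
                 color = .data$liquid)
  } else {
    ggplot2::aes(x = .data$intake_g, y = .data$total_licks)
  }
  ggplot2::ggplot(data, aes) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "Consumed liquid (g)", y = "Total licks",
                  color = "Liquid") +
    ggplot2::theme_bw()
}

#' Plot a bout raster
#'
#' Bouts as horizontal segments per channel, segment height proportional
#' to licks per bout.
#'
#' @param object A `bout_summary` from [segment_bouts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bout_summary
#' @export
autoplot.bout_summary <- function(object, ...) {
  df <- dplyr::mutate(object,
                      channel = paste0(.data$cage_id, .data$bottle_id))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$onset_ms / 1000, xend = .data$offset_ms / 1000,
    y = .data$channel, yend = .data$channel,
    linewidth = .data$n_licks
  )) +
    ggplot2::geom_segment(lineend = "butt") +
    ggplot2::scale_linewidth(range = c(0.5, 4)) +
    ggplot2::labs(x = "Time (s)", y = "Channel", linewidth = "Licks/bout") +
    ggplot2::theme_bw()
}

#' Plot a raw sensor trace with optional detections and threshold
#'
#' @param trace A `sensor_trace` tibble (one or more channels).
#' @param events Optional `lick_events` overlaid as rug marks.
#' @param threshold Optional horizontal threshold line, a.u.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, events = NULL, threshold = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_ms / 1000,
                                           y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$cage_id, .data$bottle_id)) +
    ggplot2::labs(x = "Time (s)", y = "Sensor value (a.u.)") +
    ggplot2::theme_bw()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                                 color = "red")
  }
  if (!is.null(events)) {
    p <- p + ggplot2::geom_rug(
      data = as_events_tbl(events),
      ggplot2::aes(x = .data$time_ms / 1000), inherit.aes = FALSE,
      sides = "t", color = "blue")
  }
  p
}
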