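#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Plot an inertial record
#'
#' Six-panel time trace (accelerometer and gyroscope axes), optionally shaded
#' by the labelled exercise intervals.
#'
#' @param object An [imu_record()].
#' @param track Optional `label_track` to shade exercise intervals.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.imu_record <- function(object, track = NULL, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"t",
                              names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = CHANNEL_NAMES)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value))
  if (!is.null(track) && nrow(track) > 0L) {
    shade <- tibble::as_tibble(track)
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end,
                   ymin = -Inf, ymax = Inf, fill = .data$class),
      alpha = 0.15, inherit.aes = FALSE)
  }
  p + ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = attr(object, "record_id")) +
    ggplot2::theme_minimal()
}

#' Plot per-window detection output along a record
#'
#' Shows the OOD score over window start times with the calibrated threshold
#' and, when ground truth is supplied, the true exercise windows.
#'
#' @param detection Tibble from [detect()] (columns `score`, `keep`).
#' @param start_time Window start times (seconds).
#' @param threshold Calibrated threshold to draw.
#' @param truth Optional logical ground-truth exercise mask.
#' @return A ggplot object.
#' @export
plot_detection <- function(detection, start_time, threshold = NULL, truth = NULL) {
  df <- dplyr::mutate(detection, start_time = start_time,
                      truth = if (is.null(truth)) NA else truth)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$start_time, y = .data$score))
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$truth), size = 0.8)
  } else {
    p <- p + ggplot2::geom_point(size = 0.8)
  }
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p + ggplot2::labs(x = "window start (s)", y = "OOD score",
                    colour = "exercise") +
    ggplot2::theme_minimal()
}

#' Plot an experiment summary
#'
#' Dot-and-error-bar panel of fold-mean metrics by method and grouping.
#'
#' @param summary The `summary` tibble from [run_experiment()].
#' @param task Which task to show (`"ood_clinic"`, `"classify"`,
#'   `"ood_home"`).
#' @param metric Metric to plot.
#' @return A ggplot object.
#' @export
plot_experiment_summary <- function(summary, task = "ood_clinic",
                                    metric = "auroc") {
  df <- summary[summary$task == task & summary$metric == metric, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$grouping, y = .data$mean,
                                   colour = .data$method,
                                   group = .data$method)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      width = 0.2, position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(y = metric, x = "grouping", title = task) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
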