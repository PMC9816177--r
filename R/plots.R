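#' Plot per-axis projected-PC variance ratios
#'
#' Mirrors the per-session PC-ratio panels: one point per principal
#' component, the shaded region marking the leading components that
#' capture the target fraction of unadapted variance, and a horizontal
#' reference at ratio 1.
#'
#' @param object A `ca_pc_ratio`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ca_pc_ratio
#' @export
autoplot.ca_pc_ratio <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pc, y = .data$ratio)) +
    ggplot2::annotate("rect", xmin = 0.5, xmax = object$n_pcs_90 + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "grey40") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::labs(x = "Principal component",
                  y = "Variance ratio (unadapt / adapt)",
                  title = sprintf("Mean ratio %.3f over %d leading PCs",
                                  object$mean_ratio, object$n_pcs_90)) +
    ggplot2::theme_classic()
}

#' Plot the accuracy distribution of a decoder
#'
#' @param object A `ca_decoder`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ca_decoder
#' @export
autoplot.ca_decoder <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$chance, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$mean_accuracy, colour = "red") +
    ggplot2::labs(x = "Test accuracy (%)", y = "Iterations",
                  title = sprintf("%.1f%% above chance (s.e. %.2f)",
                                  object$accuracy_above_chance, object$se)) +
    ggplot2::theme_classic()
}

#' Plot a sliding-window tuning timecourse
#'
#' @param object A `ca_timecourse` from [sliding_tuning()].
#' @param ... Unused.
#' @return A ggplot object; the dashed vertical line marks the tuning
#'   latency (first window with corrected significance), when defined.
#' @method autoplot ca_timecourse
#' @export
autoplot.ca_timecourse <- function(object, ...) {
  lat <- tuning_latency(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$window_start_ms,
                                            y = .data$csi)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70", `TRUE` = "red")) +
    ggplot2::labs(x = "Window start (ms)", y = "Selectivity index") +
    ggplot2::theme_classic()
  if (is.finite(lat)) p <- p + ggplot2::geom_vline(xintercept = lat, linetype = 2)
  p
}

#' Heatmap of a sliding-window feature map
#'
#' @param fmap A [feature_map()] result.
#' @param fill `"osi"` (orientation-selectivity heatmap) or `"label"`.
#' @return A ggplot object (y axis flipped to image convention).
#' @export
plot_feature_map <- function(fmap, fill = c("osi", "label")) {
  fill <- match.arg(fill)
  ggplot2::ggplot(fmap, ggplot2::aes(x = .data$center_col, y = .data$center_row,
                                     fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Column (px)", y = "Row (px)") +
    ggplot2::theme_minimal()
}

#' Plot tuning curves per condition
#'
#' @param curves A [tuning_curve()] tibble (optionally with a `condition`
#'   column) filtered to one neuron, or with a `neuron` column to facet.
#' @return A ggplot object with mean +/- s.e.m. responses per angle.
#' @export
plot_tuning_curve <- function(curves) {
  has_cond <- "condition" %in% names(curves)
  aes <- if (has_cond) {
    ggplot2::aes(x = .data$stimulus_angle_deg, y = .data$rate,
                 colour = .data$condition, group = .data$condition)
  } else {
    ggplot2::aes(x = .data$stimulus_angle_deg, y = .data$rate, group = 1)
  }
  p <- ggplot2::ggplot(curves, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$rate - .data$sem,
                                          ymax = .data$rate + .data$sem),
                             size = 0.2) +
    ggplot2::labs(x = "Stimulus angle (deg)", y = "Rate (spikes/s)") +
    ggplot2::theme_classic()
  if ("neuron" %in% names(curves) && length(unique(curves$neuron)) > 1) {
    p <- p + ggplot2::facet_wrap(~neuron, scales = "free_y")
  }
  p
}

#' Plot an eye-speed trace with detected fixations shaded
#'
#' @param trace An eye trace tibble (`t_ms`, `x_deg`, `y_deg`) or
#'   `ca_eye_session`.
#' @param fixations A [detect_fixations()] result.
#' @param velocity_threshold Threshold line, deg/s.
#' @return A ggplot object.
#' @export
plot_fixations <- function(trace, fixations, velocity_threshold = 100) {
  if (inherits(trace, "ca_eye_session")) trace <- trace$trace
  n <- nrow(trace)
  dt_s <- diff(trace$t_ms[1:2]) / 1000
  vx <- c(0, (trace$x_deg[3:n] - trace$x_deg[1:(n - 2)]) / 2, 0) / dt_s
  vy <- c(0, (trace$y_deg[3:n] - trace$y_deg[1:(n - 2)]) / 2, 0) / dt_s
  df <- tibble::tibble(t_ms = trace$t_ms, speed = sqrt(vx^2 + vy^2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_ms, y = .data$speed)) +
    ggplot2::geom_rect(data = fixations,
                       ggplot2::aes(xmin = .data$onset_ms, xmax = .data$offset_ms,
                                    ymin = -Inf, ymax = Inf),
                       inherit.aes = FALSE, fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = velocity_threshold, linetype = 2) +
    ggplot2::labs(x = "Time (ms)", y = "Eye speed (deg/s)") +
    ggplot2::theme_classic()
}
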