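#' Plot a signal trace
#'
#' Time series of the trace with switch phases, when annotated, shaded and
#' labelled — the switching transients of the protocol are clearly visible.
#'
#' @param object A [signal_trace()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signal_trace
#' @export
autoplot.signal_trace <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time,
                                            y = .data$voltage)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "voltage (V)")
  phases <- attr(object, "phases")
  if (!is.null(phases)) {
    p <- p +
      ggplot2::geom_vline(xintercept = phases$start, linetype = "dotted",
                          colour = "grey40") +
      ggplot2::annotate("text", x = (phases$start + phases$end) / 2,
                        y = max(object$voltage), label = phases$label,
                        vjust = -0.4, size = 3)
  }
  p
}

#' Plot a Bode table
#'
#' Magnitude response per contact resistance on log-frequency axes.
#'
#' @param table A tibble from [bode()] or [bode_report()].
#' @return A ggplot object.
#' @export
plot_bode <- function(table) {
  ggplot2::ggplot(table, ggplot2::aes(x = .data$frequency,
                                      y = .data$magnitude_db,
                                      colour = factor(.data$r_contact))) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "magnitude (dB)",
                  colour = "contact (Ohm)")
}

#' Plot an experiment report
#'
#' For grid experiments: estimated against true contact resistance on log
#' axes with the quality thresholds; for monopolar sweeps: replicate
#' boxplots of the estimates with the identity line.
#'
#' @param object An `experiment_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot experiment_report
#' @export
autoplot.experiment_report <- function(object, ...) {
  thr <- attr(object, "r_thresholds") %||% c(2500, 7500)
  if ("r_est" %in% names(object)) {
    return(
      ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$r_true),
                                           y = .data$r_est)) +
        ggplot2::geom_boxplot() +
        ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                            colour = "red") +
        ggplot2::scale_y_log10() +
        ggplot2::facet_wrap(~ .data$terminal) +
        ggplot2::labs(x = "true contact resistance (Ohm)",
                      y = "estimated (Ohm)")
    )
  }
  long <- tidyr::pivot_longer(
    dplyr::mutate(object,
                  plus_true = .data$r_plus_true,
                  minus_true = .data$r_minus_true),
    cols = c("r_plus_est", "r_minus_est"),
    names_to = "terminal", values_to = "r_est"
  )
  long$r_true <- ifelse(long$terminal == "r_plus_est",
                        long$plus_true, long$minus_true)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$r_true, y = .data$r_est,
                                     colour = .data$terminal)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "red") +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "true contact resistance (Ohm)",
                  y = "estimated (Ohm)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
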