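#' Plot a cross-correlogram
#'
#' Bar plot of the (optionally display-smoothed) correlogram with the peak
#' marked.
#'
#' @param object a `ccg` object.
#' @param smooth apply the 5-point display smoothing.
#' @param xlim_ms lag range to display.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ccg
#' @export
autoplot.ccg <- function(object, smooth = TRUE, xlim_ms = c(-50, 50), ...) {
  df <- tidy.ccg(object)
  if (smooth) df$count <- smooth_for_display(df$count)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_ms, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::geom_vline(xintercept = object$peak_lag_ms,
                        linetype = "dashed", colour = "red") +
    ggplot2::coord_cartesian(xlim = xlim_ms) +
    ggplot2::labs(x = "lag (ms)", y = "normalized count") +
    ggplot2::theme_minimal()
}

#' Plot detected synchrony events over the population count trace
#'
#' @param object a `sync_events` object.
#' @param counts optional sliding-count series to draw underneath.
#' @param sampling_rate_hz rate of `counts`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot sync_events
#' @export
autoplot.sync_events <- function(object, counts = NULL,
                                 sampling_rate_hz = 2000, ...) {
  ev <- object$events
  p <- ggplot2::ggplot()
  if (!is.null(counts)) {
    df <- tibble::tibble(t = (seq_along(counts) - 1L) / sampling_rate_hz,
                         count = counts)
    p <- p + ggplot2::geom_line(data = df,
                                ggplot2::aes(x = .data$t, y = .data$count),
                                colour = "grey50", linewidth = 0.3)
  }
  p +
    ggplot2::geom_vline(data = ev,
                        ggplot2::aes(xintercept = .data$event_time_s),
                        colour = "red", alpha = 0.6) +
    ggplot2::labs(x = "time (s)", y = "population spike count") +
    ggplot2::theme_minimal()
}

#' Plot a spatial tuning curve
#'
#' @param object a `tuning_curve` object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot tuning_curve
#' @export
autoplot.tuning_curve <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$bin_center_cm, y = .data$rate_hz)) +
    ggplot2::geom_col(width = object$track_cm / object$n_bins,
                      fill = "steelblue") +
    ggplot2::labs(x = "position (cm)", y = "rate (Hz)",
                  subtitle = sprintf("selectivity %.2f, peak %.1f Hz",
                                     object$selectivity, object$peak_rate_hz)) +
    ggplot2::theme_minimal()
}

#' Plot synchrony-triggered subVm traces
#'
#' Per-cell means in grey, grand mean in red.
#'
#' @param sts result of [synchrony_triggered_subvm()].
#' @return a ggplot.
#' @export
plot_sync_triggered_subvm <- function(sts) {
  per <- purrr::imap_dfr(
    stats::setNames(sts$per_cell$mean_trace, sts$per_cell$cell_id),
    function(tr, id) {
      tibble::tibble(cell_id = id, lag_s = sts$lag_s, subvm = tr)
    })
  grand <- tibble::tibble(lag_s = sts$lag_s, subvm = sts$grand_mean)
  ggplot2::ggplot(per, ggplot2::aes(x = .data$lag_s, y = .data$subvm,
                                    group = .data$cell_id)) +
    ggplot2::geom_line(colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_line(data = grand, ggplot2::aes(group = NULL),
                       colour = "red", linewidth = 1) +
    ggplot2::labs(x = "lag from synchrony (s)", y = "subVm (dF/F)") +
    ggplot2::theme_minimal()
}
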