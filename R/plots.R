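# ggplot2 views of signals, cumulant features, GA progress and run reports.

#' Plot a signal trace
#'
#' @param signal Numeric vector.
#' @param sampling_rate Sampling frequency in Hz (x axis in seconds).
#' @return A ggplot object.
#' @export
plot_signal <- function(signal, sampling_rate = 360) {
  check_signal(signal)
  df <- tibble(time = (seq_along(signal) - 1) / sampling_rate,
               amplitude = signal)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "amplitude")
}

#' Plot the three cumulant slices of a signal
#'
#' @param signal Numeric vector.
#' @param max_lag Maximum cumulant lag.
#' @return A ggplot object with one facet per cumulant order.
#' @export
plot_cumulants <- function(signal, max_lag) {
  lags <- -max_lag:max_lag
  df <- dplyr::bind_rows(
    tibble(order = "2nd order", lag = lags, value = cumulant2(signal, max_lag)),
    tibble(order = "3rd order", lag = lags, value = cumulant3_diag(signal, max_lag)),
    tibble(order = "4th order", lag = lags, value = cumulant4_diag(signal, max_lag))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~order, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "lag (samples)", y = "cumulant value")
}

#' @rdname autoplot.ecg_run_report
#' @param object An `ecg_run_report`.
#' @param ... Unused.
#' @export
autoplot.ecg_run_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$ga_history, c("best", "mean"),
                            names_to = "statistic", values_to = "error_rate")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$error_rate,
                                   colour = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "generation", y = "fitness (error rate)",
                  colour = NULL,
                  title = "GA progress of the evolutionary hybrid classifier")
}

#' GA-progress plot for a pipeline run
#'
#' Shows best and mean fitness (error rate) per generation.
#'
#' @name autoplot.ecg_run_report
#' @return A ggplot object.
NULL
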