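#' Plot a sampled signal
#'
#' @param object A `sampled_signal`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sampled_signal <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time [s]", y = "amplitude")
}

#' Plot an amplitude spectrum
#'
#' @param object An `amplitude_spectrum`.
#' @param ... Unused.
#' @return A ggplot of line amplitude vs frequency.
#' @export
autoplot.amplitude_spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$frequency, y = .data$amplitude)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$frequency, yend = 0),
                          linewidth = 0.3) +
    ggplot2::labs(x = "frequency [Hz]", y = "amplitude")
}

#' Plot a fit: spectrum, both baseline pairs, and the final estimate
#'
#' @param object A `dsca_fit`.
#' @param zoom_bins Half-width of the frequency window around the estimate, in
#'   bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dsca_fit <- function(object, zoom_bins = 10, ...) {
  f0 <- object$final$frequency
  df <- object$delta_f
  spec <- dplyr::filter(as_tibble(object$spectrum),
                        abs(.data$frequency - f0) <= zoom_bins * df)
  pairs <- object$rounds |>
    dplyr::select("round", "f_left", "f_right", "y_left", "y_right") |>
    tidyr::pivot_longer(
      cols = c("f_left", "f_right"),
      names_to = "side", values_to = "frequency"
    ) |>
    dplyr::mutate(amplitude = ifelse(.data$side == "f_left",
                                     .data$y_left, .data$y_right),
                  round = factor(.data$round))
  ggplot2::ggplot(spec, ggplot2::aes(x = .data$frequency, y = .data$amplitude)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$frequency, yend = 0),
                          linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_point(data = pairs, ggplot2::aes(colour = .data$round),
                        size = 2) +
    ggplot2::geom_vline(xintercept = f0, linetype = "dashed") +
    ggplot2::labs(x = "frequency [Hz]", y = "amplitude",
                  colour = "round",
                  title = sprintf("%s estimate: f = %.4f Hz",
                                  toupper(object$method), f0))
}

#' Plot a removal report: input, cleaned output and reference
#'
#' @param object A `removal_report`.
#' @param ... Unused.
#' @return A ggplot with one facet per trace.
#' @export
autoplot.removal_report <- function(object, ...) {
  traces <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(object$input), trace = "input"),
    dplyr::mutate(as_tibble(object$cleaned),
                  trace = paste0("cleaned (", object$method, ")"))
  )
  ggplot2::ggplot(traces, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~trace, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = "amplitude")
}

#' Plot a benchmark table: frequency RMSE vs normalized shift per method
#'
#' @param object A `benchmark_table`.
#' @param ... Unused.
#' @return A ggplot, facetted by SNR.
#' @export
autoplot.benchmark_table <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$delta_k, y = .data$rmse_frequency,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~snr_db, labeller = ggplot2::label_both) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(Delta * k), y = "frequency RMSE [Hz]")
}
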