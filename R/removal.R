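#' Synthesize a compensation signal from estimated parameters
#'
#' Reconstructs `A * cos(2 * pi * f * t + phi)` from an estimate so it can be
#' subtracted from the recording. Identical contract to [generate_sinusoid()].
#'
#' @inheritParams generate_sinusoid
#' @return A [sampled_signal()].
#' @export
synthesize_compensation <- function(params, sample_rate, n) {
  if (params$amplitude == 0) {
    return(sampled_signal(numeric(n), sample_rate))
  }
  generate_sinusoid(params, sample_rate, n)
}

#' Remove a power-line artifact from a signal
#'
#' For `method = "dsca"` or `"rbsc"`: estimates the artifact's harmonic
#' parameters, synthesizes the compensation sinusoid and subtracts it — a
#' purely subtractive correction with no filter transient, so
#' `cleaned + compensation` reconstructs the input exactly. For
#' `method = "notch"`: applies the causal second-order IIR notch baseline,
#' which attenuates the mains line but distorts the early samples.
#'
#' @param signal A [sampled_signal()] to clean.
#' @param method `"dsca"`, `"rbsc"` or `"notch"`.
#' @param search_band Optional Hz band for the estimator's peak search.
#' @param reference Optional clean [sampled_signal()]; when given, the report
#'   carries the Pearson correlation of the cleaned output with the reference
#'   and the RMS of their difference.
#' @param notch_hz Notch centre frequency in Hz (`method = "notch"` only);
#'   defaults to 50.
#' @param q Notch quality factor, default 30.
#' @param phase_slope Passed to the estimator.
#' @return An object of class `removal_report`: a list with `method`,
#'   `estimate` (a [harmonic_params()] row, or `NULL` for the notch),
#'   `fit` (the `dsca_fit`, or `NULL`), `cleaned` (a [sampled_signal()]),
#'   `compensation` (or `NULL`), `correlation_vs_reference` and
#'   `residual_rms` (`NA` without a reference). Inspect with [glance()].
#' @examples
#' eeg <- synth_eeg_surrogate(200, 1000, rms = 50, seed = 1)
#' pla <- generate_sinusoid(harmonic_params(50, 50.05), 200, 1000)
#' rep <- remove_pla(compose_signals(eeg, pla), reference = eeg)
#' glance(rep)
#' @export
remove_pla <- function(signal, method = c("dsca", "rbsc", "notch"),
                       search_band = NULL, reference = NULL,
                       notch_hz = 50, q = 30,
                       phase_slope = c("nominal", "exact")) {
  method <- match.arg(method)
  signal <- as_sampled_signal(signal)
  fs <- sample_rate(signal)
  n <- nrow(signal)

  fit <- NULL
  estimate <- NULL
  compensation <- NULL
  if (method == "notch") {
    cleaned <- notch_filter_baseline(signal, center_hz = notch_hz, q = q)
  } else {
    fit <- estimate_pla(signal, method = method, search_band = search_band,
                        phase_slope = phase_slope)
    estimate <- fit$final
    compensation <- synthesize_compensation(estimate, fs, n)
    cleaned <- sampled_signal(signal$value - compensation$value, fs)
  }

  correlation <- NA_real_
  residual_rms <- NA_real_
  if (!is.null(reference)) {
    reference <- as_sampled_signal(reference)
    if (nrow(reference) != n) abort("`reference` must match the signal length.")
    correlation <- correlation_coefficient(cleaned, reference)
    residual_rms <- sqrt(mean((cleaned$value - reference$value)^2))
  }

  structure(
    list(
      method = method,
      estimate = estimate,
      fit = fit,
      cleaned = cleaned,
      compensation = compensation,
      input = signal,
      correlation_vs_reference = correlation,
      residual_rms = residual_rms
    ),
    class = "removal_report"
  )
}

#' Causal IIR notch-filter baseline
#'
#' The comparison baseline: a second-order constrained notch (unit gain at DC
#' and Nyquist, -3 dB bandwidth `center_hz / q`) applied causally, forward
#' only. Its start-up transient is precisely the time-domain distortion that
#' subtractive compensation avoids.
#'
#' @param signal A [sampled_signal()].
#' @param center_hz Notch centre in Hz, strictly inside `(0, Nyquist)`.
#' @param q Quality factor (> 0), default 30.
#' @return The filtered [sampled_signal()].
#' @export
notch_filter_baseline <- function(signal, center_hz, q = 30) {
  signal <- as_sampled_signal(signal)
  fs <- sample_rate(signal)
  if (center_hz <= 0 || center_hz >= fs / 2) {
    abort(sprintf(
      "notch centre (%g Hz) must lie strictly inside (0, Nyquist = %g Hz).",
      center_hz, fs / 2
    ))
  }
  if (q <= 0) abort("`q` must be > 0.")
  co <- notch_coef(center_hz, fs, q)
  sampled_signal(biquad_filter(signal$value, co$b, co$a), fs)
}

#' Pearson correlation of two signals
#'
#' @param a,b Two [sampled_signal()]s (or data frames with a `value` column)
#'   of equal length, neither constant.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
correlation_coefficient <- function(a, b) {
  va <- if (is.data.frame(a)) a$value else a
  vb <- if (is.data.frame(b)) b$value else b
  if (length(va) != length(vb)) abort("signals must have equal length.")
  if (length(va) < 2) abort("need at least 2 samples.")
  if (sd(va) == 0 || sd(vb) == 0) {
    abort("correlation is undefined for a constant signal.")
  }
  cor(va, vb)
}

#' Signal-to-noise ratio between two signals, in dB
#'
#' `10 * log10(P_signal / P_noise)` with mean-square powers.
#'
#' @param signal,noise Two [sampled_signal()]s of equal length.
#' @return SNR in dB.
#' @export
snr_db_between <- function(signal, noise) {
  vs <- if (is.data.frame(signal)) signal$value else signal
  vn <- if (is.data.frame(noise)) noise$value else noise
  if (length(vs) != length(vn)) abort("signals must have equal length.")
  pn <- mean(vn^2)
  if (pn == 0) abort("SNR is undefined against zero-power noise.")
  10 * log10(mean(vs^2) / pn)
}

#' @export
print.removal_report <- function(x, ...) {
  cat(sprintf("<removal_report> method = %s, N = %d, fs = %g Hz\n",
              x$method, nrow(x$cleaned), sample_rate(x$cleaned)))
  if (!is.null(x$estimate)) {
    cat(sprintf("  estimate: A = %.6g, f = %.6f Hz, phi = %.6f rad\n",
                x$estimate$amplitude, x$estimate$frequency, x$estimate$phase))
  }
  if (!is.na(x$correlation_vs_reference)) {
    cat(sprintf("  vs reference: correlation = %.6f, residual RMS = %.6g\n",
                x$correlation_vs_reference, x$residual_rms))
  }
  invisible(x)
}

#' One-row summary of a removal report
#'
#' @param x A `removal_report`.
#' @param ... Unused.
#' @return A one-row tibble: method, estimated parameters (`NA` for the
#'   notch), correlation with the reference and residual RMS (`NA` without a
#'   reference).
#' @export
glance.removal_report <- function(x, ...) {
  tibble(
    method = x$method,
    amplitude = if (is.null(x$estimate)) NA_real_ else x$estimate$amplitude,
    frequency = if (is.null(x$estimate)) NA_real_ else x$estimate$frequency,
    phase = if (is.null(x$estimate)) NA_real_ else x$estimate$phase,
    correlation_vs_reference = x$correlation_vs_reference,
    residual_rms = x$residual_rms
  )
}
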