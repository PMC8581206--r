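#' Generate a sampled sinusoid
#'
#' Synthesises `A * cos(2 * pi * f * n / fs + phi)` for `n = 0 .. n_samples-1`.
#' This is both the power-line artifact model used throughout and the
#' compensation signal of the removal step.
#'
#' @param params A [harmonic_params()] row (or a list with `amplitude`,
#'   `frequency`, `phase`).
#' @param sample_rate Sampling rate `fs` in Hz.
#' @param n Number of samples (>= 2).
#' @return A [sampled_signal()].
#' @examples
#' pla <- generate_sinusoid(harmonic_params(1, 250.05, 0), sample_rate = 1000, n = 1000)
#' @export
generate_sinusoid <- function(params, sample_rate, n) {
  amplitude <- params$amplitude
  frequency <- params$frequency
  phase <- params$phase %||% 0
  if (n < 2) abort("`n` must be at least 2.")
  if (amplitude < 0) abort("`amplitude` must be >= 0.")
  if (frequency <= 0 || frequency >= sample_rate / 2) {
    abort(sprintf(
      "`frequency` (%g Hz) must lie strictly inside (0, Nyquist = %g Hz).",
      frequency, sample_rate / 2
    ))
  }
  idx <- 0:(n - 1)
  sampled_signal(
    amplitude * cos(2 * pi * frequency * idx / sample_rate + phase),
    sample_rate = sample_rate
  )
}

#' Add white Gaussian noise at a target SNR
#'
#' The noise standard deviation is derived from the realized root-mean-square
#' of the input: `sigma = rms(signal) * 10^(-snr_db / 20)`, so that the
#' mean-square power ratio `10 * log10(P_signal / P_noise)` equals `snr_db` in
#' expectation. `snr_db = Inf` returns the input unchanged.
#'
#' @param signal A [sampled_signal()].
#' @param snr_db Target signal-to-noise ratio in dB (may be `Inf`).
#' @param seed Integer seed; the draw is reproducible and leaves the global
#'   RNG state untouched.
#' @return A new [sampled_signal()]; the input is not modified.
#' @export
add_gaussian_noise <- function(signal, snr_db, seed) {
  signal <- as_sampled_signal(signal)
  if (is.infinite(snr_db) && snr_db > 0) return(signal)
  if (!is.finite(snr_db)) abort("`snr_db` must be finite or +Inf.")
  rms <- sqrt(mean(signal$value^2))
  if (rms == 0) abort("SNR is undefined for an all-zero signal.")
  sigma <- rms * 10^(-snr_db / 20)
  noise <- withr::with_seed(as.integer(seed), rnorm(nrow(signal), sd = sigma))
  sampled_signal(signal$value + noise, sample_rate(signal))
}

#' Band-limited EEG-like surrogate signal
#'
#' White Gaussian noise passed forward-backward through a Butterworth band-pass
#' (second-order high-pass and low-pass sections at the stated corners), then
#' scaled to a target RMS. This emulates the only property the clinical
#' acquisition chain guarantees: a band-pass of `[0.5, 70]` Hz. It carries no
#' physiological structure (no rhythms, no nonstationarity).
#'
#' @param sample_rate Sampling rate in Hz.
#' @param n Number of samples.
#' @param band Length-2 numeric, band-pass corners in Hz; must satisfy
#'   `0 < low < high < sample_rate / 2`.
#' @param rms Target root-mean-square amplitude of the output.
#' @param seed Integer seed; output is deterministic per seed.
#' @return A [sampled_signal()].
#' @export
synth_eeg_surrogate <- function(sample_rate, n, band = c(0.5, 70), rms = 1,
                                seed) {
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= sample_rate / 2) {
    abort(sprintf(
      "`band` must satisfy 0 < low < high < Nyquist = %g Hz.", sample_rate / 2
    ))
  }
  pad <- max(200L, ceiling(2 * sample_rate / band[1]))
  white <- withr::with_seed(as.integer(seed), rnorm(n + 2 * pad))
  lp <- butter2_coef(band[2], sample_rate, "low")
  hp <- butter2_coef(band[1], sample_rate, "high")
  bandpass <- function(x) biquad_filter(biquad_filter(x, lp$b, lp$a), hp$b, hp$a)
  y <- rev(bandpass(rev(bandpass(white))))
  y <- y[(pad + 1):(pad + n)]
  y <- y * rms / sqrt(mean(y^2))
  sampled_signal(y, sample_rate)
}

#' Superimpose two signals
#'
#' Element-wise sum of two signals with identical length and sampling rate —
#' the contaminated-recording model `x(t) = eeg(t) + pla(t)`.
#'
#' @param clean,artifact Two [sampled_signal()]s of equal length and rate.
#' @return A [sampled_signal()] holding the sample-wise sum.
#' @export
compose_signals <- function(clean, artifact) {
  clean <- as_sampled_signal(clean)
  artifact <- as_sampled_signal(artifact)
  if (nrow(clean) != nrow(artifact)) {
    abort("signals must have the same number of samples.")
  }
  fs1 <- sample_rate(clean)
  fs2 <- sample_rate(artifact)
  if (abs(fs1 - fs2) > 1e-9 * fs1) {
    abort("signals must share the same sampling rate.")
  }
  sampled_signal(clean$value + artifact$value, fs1)
}
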