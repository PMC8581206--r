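#' Single-sided amplitude-normalized spectrum
#'
#' Computes the FFT (negative-exponent convention) of a signal and scales it to
#' single-sided amplitude: interior bins are multiplied by `2/N`, the DC bin —
#' and the Nyquist bin when `N` is even — by `1/N`. With this normalization a
#' noise-free on-grid sinusoid of amplitude `A` shows line amplitude `A` at its
#' frequency.
#'
#' @param signal A [sampled_signal()].
#' @return A tibble of class `amplitude_spectrum` with one row per bin
#'   `l = 0 .. floor(N/2)` and columns `frequency` (Hz, `l * fs / N`),
#'   `amplitude`, `phase` and the complex `coefficient`. Attributes `delta_f`
#'   (bin spacing `fs/N`), `source_n` and `sample_rate` are attached.
#' @examples
#' pla <- generate_sinusoid(harmonic_params(1, 250.05), 1000, 1000)
#' spec <- compute_spectrum(pla)
#' spec[spec$frequency %in% c(250, 251), ]
#' @export
compute_spectrum <- function(signal) {
  signal <- as_sampled_signal(signal)
  n <- nrow(signal)
  fs <- sample_rate(signal)
  coefs <- fft(signal$value)
  n_half <- floor(n / 2)
  scale <- rep(2 / n, n_half + 1)
  scale[1] <- 1 / n
  if (n %% 2 == 0) scale[n_half + 1] <- 1 / n
  coefs <- coefs[seq_len(n_half + 1)] * scale
  out <- tibble(
    frequency = (0:n_half) * fs / n,
    amplitude = Mod(coefs),
    phase = wrap_phase(Arg(coefs)),
    coefficient = coefs
  )
  attr(out, "delta_f") <- fs / n
  attr(out, "source_n") <- n
  attr(out, "sample_rate") <- fs
  class(out) <- c("amplitude_spectrum", class(out))
  out
}

# bin spacing of a spectrum, robust to attribute stripping
spectrum_delta_f <- function(spectrum) {
  df <- attr(spectrum, "delta_f")
  if (!is.null(df)) return(df)
  if (is.data.frame(spectrum) && nrow(spectrum) >= 2) {
    return(spectrum$frequency[2] - spectrum$frequency[1])
  }
  abort("cannot determine the bin spacing of this spectrum.")
}

#' Evaluate a single spectral line at an arbitrary frequency
#'
#' Direct discrete-time Fourier transform sum
#' `(2/N) * sum_n x[n] * exp(-2i * pi * f * n / fs)` — the value
#' [compute_spectrum()] would report if its grid contained `frequency`. Needed
#' by the dual-step correction, whose second round reads two lines half a bin
#' either side of the first-round frequency, generally off the FFT grid.
#'
#' @param signal A [sampled_signal()].
#' @param frequency Frequency in Hz, strictly inside `(0, Nyquist)`.
#' @return A one-row tibble of class `spectral_line` with columns `frequency`,
#'   `amplitude`, `phase`.
#' @export
evaluate_dtft_line <- function(signal, frequency) {
  signal <- as_sampled_signal(signal)
  fs <- sample_rate(signal)
  if (frequency <= 0 || frequency >= fs / 2) {
    abort(sprintf(
      "`frequency` (%g Hz) must lie strictly inside (0, Nyquist = %g Hz).",
      frequency, fs / 2
    ))
  }
  n <- nrow(signal)
  idx <- 0:(n - 1)
  coef <- sum(signal$value * exp(-2i * pi * frequency * idx / fs)) * 2 / n
  out <- tibble(
    frequency = frequency,
    amplitude = Mod(coef),
    phase = wrap_phase(Arg(coef))
  )
  class(out) <- c("spectral_line", class(out))
  out
}

#' Locate the pair of baseline spectral lines around the artifact peak
#'
#' Finds the interior bin of maximum amplitude (optionally restricted to a
#' search band), pairs it with whichever neighbour has the larger amplitude,
#' and orders the pair by frequency. For an off-grid tone the two lines then
#' bracket the true frequency: `f_left <= f_c < f_right` with
#' `f_right - f_left` equal to one bin. When the two neighbours tie to within
#' `1e-12` relative, the right neighbour is chosen so that on-grid tones give
#' the deterministic pair `(k, k+1)`.
#'
#' @param spectrum An `amplitude_spectrum` from [compute_spectrum()].
#' @param search_band Optional length-2 numeric `(low, high)` in Hz limiting
#'   the peak search, e.g. `c(45, 65)` for mains interference.
#' @return A two-row tibble of class `bssl_pair` (rows `left`, `right`) with
#'   columns `side`, `frequency`, `amplitude`, `phase`; attributes `delta_f`
#'   and `source_n` are carried over.
#' @export
locate_bssl <- function(spectrum, search_band = NULL) {
  if (nrow(spectrum) < 4) abort("the spectrum needs at least 4 bins.")
  df <- spectrum_delta_f(spectrum)
  usable <- 2:(nrow(spectrum) - 1) # interior bins: need both neighbours
  if (!is.null(search_band)) {
    usable <- usable[spectrum$frequency[usable] >= search_band[1] &
                       spectrum$frequency[usable] <= search_band[2]]
    if (length(usable) < 3) {
      abort("the search band must contain at least 3 interior bins.")
    }
  }
  k <- usable[which.max(spectrum$amplitude[usable])]
  y_lo <- spectrum$amplitude[k - 1]
  y_hi <- spectrum$amplitude[k + 1]
  # tie-break: equal neighbours means the tone sits on bin k; take (k, k+1)
  right_of_peak <- y_hi >= y_lo || abs(y_lo - y_hi) < 1e-12 * spectrum$amplitude[k]
  rows <- if (right_of_peak) c(k, k + 1) else c(k - 1, k)
  out <- tibble(
    side = c("left", "right"),
    frequency = spectrum$frequency[rows],
    amplitude = spectrum$amplitude[rows],
    phase = spectrum$phase[rows]
  )
  attr(out, "delta_f") <- df
  attr(out, "source_n") <- attr(spectrum, "source_n")
  class(out) <- c("bssl_pair", class(out))
  out
}
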