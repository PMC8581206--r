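#' Normalized frequency shift from a pair of baseline spectral lines
#'
#' The ratio-based correction turns the amplitudes `y_l`, `y_r` of two spectral
#' lines one bin apart into the tone's sub-bin offset above the left line:
#' `delta_k = y_r / (y_l + y_r) = (f_c - f_l) / delta_f`, in `[0, 1)`. A tone
#' exactly on the left line gives 0; symmetric leakage (`y_l = y_r`) gives 1/2.
#'
#' @param pair A `bssl_pair` from [locate_bssl()] (or any two-row data frame
#'   with an `amplitude` column ordered left, right).
#' @return The normalized frequency shift, a number in `[0, 1)`.
#' @export
rbsc_delta_k <- function(pair) {
  y_l <- pair$amplitude[1]
  y_r <- pair$amplitude[2]
  if (y_l < 0 || y_r < 0) abort("line amplitudes must be >= 0.")
  if (y_l + y_r == 0) abort("both line amplitudes are zero: no tone to correct.")
  y_r / (y_l + y_r)
}

#' Ratio-based spectrum correction (single round)
#'
#' Recovers the harmonic parameters of an off-grid sinusoid from its two
#' baseline spectral lines under the rectangular-window leakage model:
#' \deqn{A = y_l \cdot \pi\Delta k / \sin(\pi\Delta k), \quad
#'       f = f_l + \Delta k \cdot \Delta f, \quad
#'       \phi = \arg(Y_l) - \pi \Delta k \cdot \kappa,}
#' where the sinc factor is taken as 1 in the removable limit
#' `delta_k -> 0`. The phase-slope factor `kappa` defaults to 1; the
#' `"exact"` option uses the full rectangular-window slope `(N-1)/N`, an
#' `O(pi * delta_k / N)` refinement invisible at ordinary precision.
#'
#' @inheritParams rbsc_delta_k
#' @param delta_f Bin spacing in Hz; defaults to the pair's `delta_f`
#'   attribute.
#' @param phase_slope `"nominal"` (`kappa = 1`) or `"exact"`
#'   (`kappa = (N-1)/N`, requires `n`).
#' @param n Record length `N`; defaults to the pair's `source_n` attribute.
#'   Only needed for `phase_slope = "exact"`.
#' @return A [harmonic_params()] row.
#' @examples
#' pla <- generate_sinusoid(harmonic_params(1, 250.05), 1000, 1000)
#' rbsc_estimate(locate_bssl(compute_spectrum(pla)))
#' @export
rbsc_estimate <- function(pair, delta_f = NULL,
                          phase_slope = c("nominal", "exact"), n = NULL) {
  phase_slope <- match.arg(phase_slope)
  delta_f <- delta_f %||% attr(pair, "delta_f")
  if (is.null(delta_f)) {
    abort("`delta_f` is required when the pair carries no `delta_f` attribute.")
  }
  dk <- rbsc_delta_k(pair)
  sinc_corr <- if (dk < 1e-12) 1 else pi * dk / sin(pi * dk)
  kappa <- 1
  if (phase_slope == "exact") {
    n <- n %||% attr(pair, "source_n")
    if (is.null(n)) abort("`n` is required for phase_slope = \"exact\".")
    kappa <- (n - 1) / n
  }
  harmonic_params(
    amplitude = pair$amplitude[1] * sinc_corr,
    frequency = pair$frequency[1] + dk * delta_f,
    phase = wrap_phase(pair$phase[1] - pi * dk * kappa)
  )
}

#' Dual-step spectrum-correction estimate of a power-line tone
#'
#' Two-pass estimator. Round 1 runs the ratio-based correction on the FFT
#' spectrum's baseline pair. When the tone sits close to a bin (`delta_k` near
#' 0), one of those lines has low amplitude and is fragile under noise; round 2
#' therefore re-evaluates two spectral lines at exactly `f1 - delta_f/2` and
#' `f1 + delta_f/2` around the round-1 frequency — both carrying high amplitude
#' (`delta_k` near 1/2) — and reruns the correction on that off-grid pair. The
#' final parameters merge the rounds: amplitude from round 1, frequency and
#' phase from round 2. No iteration beyond these two fixed rounds is performed.
#'
#' @param signal A [sampled_signal()] containing (at least) one dominant tone.
#' @param search_band Optional length-2 Hz band for the round-1 peak search
#'   (e.g. `c(45, 65)` when cleaning mains interference).
#' @param phase_slope Phase-slope convention passed to [rbsc_estimate()].
#' @return An object of class `dsca_fit`: a list with
#'   \describe{
#'     \item{rounds}{tibble, one row per round: the pair frequencies and
#'       amplitudes, the ratio `y_l/y_r`, `delta_k`, and the round's parameter
#'       estimates;}
#'     \item{final}{the merged [harmonic_params()];}
#'     \item{spectrum}{the round-1 `amplitude_spectrum`;}
#'     \item{delta_f, sample_rate, n}{problem geometry.}
#'   }
#'   Inspect with [tidy()], [glance()], [autoplot()].
#' @examples
#' pla <- generate_sinusoid(harmonic_params(1, 250.05), 1000, 1000)
#' fit <- dsca_estimate(pla)
#' glance(fit)
#' @export
dsca_estimate <- function(signal, search_band = NULL,
                          phase_slope = c("nominal", "exact")) {
  phase_slope <- match.arg(phase_slope)
  signal <- as_sampled_signal(signal)
  fs <- sample_rate(signal)
  n <- nrow(signal)
  df <- fs / n

  spectrum <- compute_spectrum(signal)
  pair1 <- locate_bssl(spectrum, search_band = search_band)
  est1 <- rbsc_estimate(pair1, phase_slope = phase_slope)

  f_left2 <- est1$frequency - df / 2
  f_right2 <- est1$frequency + df / 2
  if (f_left2 <= 0 || f_right2 >= fs / 2) {
    abort("round-2 line frequencies fall outside (0, Nyquist); widen the record or the search band.")
  }
  left2 <- evaluate_dtft_line(signal, f_left2)
  right2 <- evaluate_dtft_line(signal, f_right2)
  pair2 <- tibble(
    side = c("left", "right"),
    frequency = c(left2$frequency, right2$frequency),
    amplitude = c(left2$amplitude, right2$amplitude),
    phase = c(left2$phase, right2$phase)
  )
  attr(pair2, "delta_f") <- df
  attr(pair2, "source_n") <- n
  class(pair2) <- c("bssl_pair", class(pair2))
  est2 <- rbsc_estimate(pair2, phase_slope = phase_slope)

  round_row <- function(idx, pair, est) {
    tibble(
      round = idx,
      f_left = pair$frequency[1], f_right = pair$frequency[2],
      y_left = pair$amplitude[1], y_right = pair$amplitude[2],
      ratio = pair$amplitude[1] / pair$amplitude[2],
      delta_k = rbsc_delta_k(pair),
      amplitude = est$amplitude, frequency = est$frequency, phase = est$phase
    )
  }
  structure(
    list(
      rounds = dplyr::bind_rows(round_row(1L, pair1, est1),
                                round_row(2L, pair2, est2)),
      final = harmonic_params(est1$amplitude, est2$frequency, est2$phase),
      spectrum = spectrum,
      delta_f = df,
      sample_rate = fs,
      n = n,
      method = "dsca"
    ),
    class = "dsca_fit"
  )
}

#' Single-round ratio-correction fit of a signal
#'
#' Convenience wrapper running one FFT, the baseline-pair location and one
#' ratio correction — the classical single-pass estimator that the dual-step
#' method improves on. Returned in the same `dsca_fit` container (with one
#' round) so the same tidiers and plots apply.
#'
#' @inheritParams dsca_estimate
#' @return A `dsca_fit` with a single round and `method = "rbsc"`.
#' @export
rbsc_fit <- function(signal, search_band = NULL,
                     phase_slope = c("nominal", "exact")) {
  phase_slope <- match.arg(phase_slope)
  signal <- as_sampled_signal(signal)
  fs <- sample_rate(signal)
  n <- nrow(signal)
  spectrum <- compute_spectrum(signal)
  pair1 <- locate_bssl(spectrum, search_band = search_band)
  est1 <- rbsc_estimate(pair1, phase_slope = phase_slope)
  structure(
    list(
      rounds = tibble(
        round = 1L,
        f_left = pair1$frequency[1], f_right = pair1$frequency[2],
        y_left = pair1$amplitude[1], y_right = pair1$amplitude[2],
        ratio = pair1$amplitude[1] / pair1$amplitude[2],
        delta_k = rbsc_delta_k(pair1),
        amplitude = est1$amplitude, frequency = est1$frequency,
        phase = est1$phase
      ),
      final = est1,
      spectrum = spectrum,
      delta_f = fs / n,
      sample_rate = fs,
      n = n,
      method = "rbsc"
    ),
    class = "dsca_fit"
  )
}

#' Estimate power-line artifact parameters
#'
#' Front-end dispatching to the dual-step ([dsca_estimate()]) or single-round
#' ([rbsc_fit()]) estimator.
#'
#' @inheritParams dsca_estimate
#' @param method `"dsca"` (default) or `"rbsc"`.
#' @return A `dsca_fit`.
#' @export
estimate_pla <- function(signal, method = c("dsca", "rbsc"),
                         search_band = NULL,
                         phase_slope = c("nominal", "exact")) {
  method <- match.arg(method)
  if (method == "dsca") {
    dsca_estimate(signal, search_band, phase_slope)
  } else {
    rbsc_fit(signal, search_band, phase_slope)
  }
}

#' @export
print.dsca_fit <- function(x, ...) {
  cat(sprintf(
    "<%s fit>  fs = %g Hz, N = %d, delta_f = %g Hz\n",
    toupper(x$method), x$sample_rate, x$n, x$delta_f
  ))
  print(as_tibble(x$rounds))
  cat(sprintf(
    "final: A = %.6g, f = %.6f Hz, phi = %.6f rad\n",
    x$final$amplitude, x$final$frequency, x$final$phase
  ))
  invisible(x)
}

#' Tidy the per-round estimates of a fit
#'
#' @param x A `dsca_fit`.
#' @param ... Unused.
#' @return A tibble with one row per estimation round plus a `"final"` row
#'   holding the merged parameters.
#' @export
tidy.dsca_fit <- function(x, ...) {
  rounds <- dplyr::mutate(x$rounds, term = paste0("round", .data$round),
                          .before = 1)
  final <- tibble(
    term = "final", round = NA_integer_,
    f_left = NA_real_, f_right = NA_real_,
    y_left = NA_real_, y_right = NA_real_,
    ratio = NA_real_, delta_k = NA_real_,
    amplitude = x$final$amplitude,
    frequency = x$final$frequency,
    phase = x$final$phase
  )
  dplyr::bind_rows(rounds, final)
}

#' One-row summary of a fit
#'
#' @param x A `dsca_fit`.
#' @param ... Unused.
#' @return A one-row tibble: method, merged amplitude/frequency/phase, the
#'   round-1 `delta_k` and the problem geometry.
#' @export
glance.dsca_fit <- function(x, ...) {
  tibble(
    method = x$method,
    amplitude = x$final$amplitude,
    frequency = x$final$frequency,
    phase = x$final$phase,
    delta_k = x$rounds$delta_k[1],
    sample_rate = x$sample_rate,
    n = x$n
  )
}
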