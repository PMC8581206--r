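#' Construct a uniformly sampled signal
#'
#' A sampled signal is stored as a tibble with a `time` column (seconds,
#' `t = 0` at the first sample) and a `value` column (signal units, e.g.
#' microvolts). The sampling rate is carried in the `"sample_rate"` attribute
#' and, redundantly, in the spacing of the `time` column, so the rate survives
#' dplyr verbs that strip attributes.
#'
#' @param values Numeric vector of at least two finite samples.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @return A tibble of class `sampled_signal` with columns `time` and `value`.
#' @examples
#' sampled_signal(sin(2 * pi * 5 * (0:99) / 100), sample_rate = 100)
#' @export
sampled_signal <- function(values, sample_rate) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    abort("a sampled signal needs at least 2 samples.")
  }
  if (!all(is.finite(values))) {
    abort("all samples must be finite.")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    abort("`sample_rate` must be a single positive number (Hz).")
  }
  out <- tibble(
    time = seq_along(values) - 1,
    value = values
  )
  out$time <- out$time / sample_rate
  attr(out, "sample_rate") <- sample_rate
  class(out) <- c("sampled_signal", class(out))
  out
}

#' Sampling rate of a signal
#'
#' Reads the `"sample_rate"` attribute when present and otherwise recovers the
#' rate from the spacing of the `time` column, so plain tibbles that have been
#' through attribute-stripping verbs still work.
#'
#' @param x A `sampled_signal` or any data frame with a uniform `time` column.
#' @return Sampling rate in Hz.
#' @export
sample_rate <- function(x) {
  fs <- attr(x, "sample_rate")
  if (!is.null(fs)) return(fs)
  if (is.data.frame(x) && "time" %in% names(x) && nrow(x) >= 2) {
    span <- x$time[nrow(x)] - x$time[1]
    if (span > 0) return((nrow(x) - 1) / span)
  }
  abort("cannot determine the sampling rate: no `sample_rate` attribute and no usable `time` column.")
}

#' Number of samples in a signal
#' @param x A `sampled_signal`.
#' @return Integer sample count N.
#' @export
n_samples <- function(x) nrow(x)

#' Extract the sample values of a signal as a plain vector
#' @param x A `sampled_signal`.
#' @return Numeric vector of samples.
#' @export
signal_values <- function(x) x$value

# coerce a data frame with time/value columns back to a sampled_signal
as_sampled_signal <- function(x) {
  if (inherits(x, "sampled_signal")) return(x)
  if (is.data.frame(x) && all(c("time", "value") %in% names(x))) {
    return(sampled_signal(x$value, sample_rate(x)))
  }
  abort("expected a `sampled_signal` (tibble with `time` and `value` columns).")
}

#' Harmonic parameters of a sinusoid
#'
#' The triple (amplitude, frequency, phase) uniquely defines the sinusoid
#' `A * cos(2 * pi * f * t + phi)`. The phase is wrapped to `(-pi, pi]` on
#' construction.
#'
#' @param amplitude Amplitude in signal units (>= 0).
#' @param frequency Frequency in Hz (> 0).
#' @param phase Phase in radians; wrapped to `(-pi, pi]`.
#' @return A one-row tibble of class `harmonic_params` with columns
#'   `amplitude`, `frequency`, `phase`.
#' @examples
#' harmonic_params(amplitude = 1, frequency = 250.05, phase = 0)
#' @export
harmonic_params <- function(amplitude, frequency, phase = 0) {
  if (!is.finite(amplitude) || amplitude < 0) {
    abort("`amplitude` must be finite and >= 0.")
  }
  if (!is.finite(frequency) || frequency <= 0) {
    abort("`frequency` must be finite and > 0 Hz.")
  }
  out <- tibble(
    amplitude = as.numeric(amplitude),
    frequency = as.numeric(frequency),
    phase = wrap_phase(as.numeric(phase))
  )
  class(out) <- c("harmonic_params", class(out))
  out
}

#' Wrap an angle to the interval (-pi, pi]
#'
#' @param x Numeric vector of angles in radians.
#' @return Angles wrapped to `(-pi, pi]`.
#' @export
wrap_phase <- function(x) {
  w <- x - 2 * pi * round(x / (2 * pi))
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}
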