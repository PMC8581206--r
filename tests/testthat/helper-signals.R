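# shared fixtures, all generated in code

# the worked-example tone: unit amplitude, 250.05 Hz, zero phase, fs = N = 1000
worked_example_tone <- function() {
  generate_sinusoid(harmonic_params(1, 250.05, 0), sample_rate = 1000, n = 1000)
}

# random tone parameters drawn reproducibly inside a frequency band
random_tones <- function(n_tones, f_range = c(100, 400), seed = 421) {
  withr::with_seed(seed, {
    tibble::tibble(
      amplitude = stats::runif(n_tones, 0.5, 5),
      frequency = stats::runif(n_tones, f_range[1], f_range[2]),
      phase = stats::runif(n_tones, -pi, pi * 0.999)
    )
  })
}
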