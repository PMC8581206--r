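test_that("compensation synthesis cancels a pure tone and handles A = 0", {
  tone <- worked_example_tone()
  fit <- dsca_estimate(tone)
  comp <- synthesize_compensation(fit$final, 1000, 1000)
  residual <- tone$value - comp$value
  expect_lt(sqrt(mean(residual^2)), 1e-2) # < 1e-2 * A

  zero <- synthesize_compensation(harmonic_params(0, 50), 200, 100)
  expect_equal(zero$value, rep(0, 100))

  # the case-study reconstruction (Nyquist-consistent mains-like frequency)
  case <- synthesize_compensation(harmonic_params(50.006, 50.05, -0.023), 200, 1000)
  expect_equal(nrow(case), 1000)
  expect_equal(case$value[1], 50.006 * cos(-0.023))
})

test_that("subtractive removal is exactly invertible and leaves a tiny residual", {
  tone <- worked_example_tone()
  report <- remove_pla(tone, method = "dsca")
  expect_lt(sqrt(mean(report$cleaned$value^2)) / sqrt(mean(tone$value^2)), 1e-2)
  # cleaned + compensation reconstructs the input to the last floating bit or
  # one ulp (the subtract-then-add round trip is not exactly associative)
  expect_lt(max(abs(report$cleaned$value + report$compensation$value -
                      tone$value)), 1e-15)
})

test_that("what removal takes out is spectrally concentrated at the tone", {
  # near-bin tone (delta_k = 0.05, the hard operating point): leakage tails
  # hold >99% of the removed power within +/- 2 bins of the estimate; tones
  # near mid-bin spread wider (~95% at delta_k = 0.25), a property of
  # rectangular-window leakage, not of the removal
  eeg <- synth_eeg_surrogate(200, 1000, band = c(0.5, 70), rms = 20, seed = 2)
  tone <- generate_sinusoid(harmonic_params(50, 50.01), 200, 1000)
  report <- remove_pla(compose_signals(eeg, tone), method = "dsca",
                       search_band = c(45, 65))
  removed <- sampled_signal(report$compensation$value, 200)
  spec <- compute_spectrum(removed)
  near <- abs(spec$frequency - report$estimate$frequency) <= 2 * 0.2
  expect_gt(sum(spec$amplitude[near]^2) / sum(spec$amplitude^2), 0.99)
})

test_that("the notch baseline passes DC, bites at its centre, and rings in early samples", {
  dc <- sampled_signal(rep(2.5, 3000), 1000)
  filtered <- notch_filter_baseline(dc, 50, q = 30)
  expect_lt(abs(filtered$value[3000] - 2.5), 1e-6)

  probe <- generate_sinusoid(harmonic_params(1, 50), 1000, 2000)
  out <- notch_filter_baseline(probe, 50, q = 30)
  # steady-state attenuation, measured on the second half (past the transient)
  a_in <- evaluate_dtft_line(sampled_signal(probe$value[1001:2000], 1000), 50)
  a_out <- evaluate_dtft_line(sampled_signal(out$value[1001:2000], 1000), 50)
  expect_gt(20 * log10(a_in$amplitude / a_out$amplitude), 30)

  # the start-up transient: ideal steady state for an on-centre tone is zero
  short <- notch_filter_baseline(generate_sinusoid(harmonic_params(1, 50), 1000, 1000),
                                 50, q = 30)
  rms_head <- sqrt(mean(short$value[1:50]^2))
  rms_tail <- sqrt(mean(short$value[951:1000]^2))
  expect_gt(rms_head, rms_tail)

  expect_error(notch_filter_baseline(probe, 600), "Nyquist")
  expect_error(notch_filter_baseline(probe, 50, q = 0), "q")
})

test_that("subtraction beats the causal notch on surrogate composites (sign test over 20 seeds)", {
  tone <- generate_sinusoid(harmonic_params(50, 50.05), 200, 1000)
  rms_eeg <- 50 / sqrt(2) * 10^(3.430 / 20) # composite SNR = the case study's
  wins <- vapply(1:20, function(seed) {
    eeg <- synth_eeg_surrogate(200, 1000, band = c(0.5, 70), rms = rms_eeg,
                               seed = seed)
    x <- compose_signals(eeg, tone)
    dsca <- remove_pla(x, "dsca", search_band = c(45, 65), reference = eeg)
    notch <- remove_pla(x, "notch", notch_hz = 50, reference = eeg)
    dsca$correlation_vs_reference > notch$correlation_vs_reference
  }, logical(1))
  # one-sided sign test: subtraction wins on significantly more than half
  p <- stats::binom.test(sum(wins), 20, 0.5, alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("correlation and SNR metrics behave on trivial and seeded inputs", {
  x <- synth_eeg_surrogate(200, 500, seed = 9)
  expect_equal(correlation_coefficient(x, x), 1)
  neg <- sampled_signal(-x$value, 200)
  expect_equal(correlation_coefficient(x, neg), -1)
  noisy <- add_gaussian_noise(x, snr_db = 40, seed = 10)
  expect_gt(correlation_coefficient(x, noisy), 0.99)
  flat <- sampled_signal(rep(1, 500), 200)
  expect_error(correlation_coefficient(x, flat), "constant")

  expect_equal(snr_db_between(x, x), 0)
  tone <- generate_sinusoid(harmonic_params(1, 123.4), 1000, 100000)
  noise <- sampled_signal(
    withr::with_seed(4, rnorm(100000, sd = 1 / sqrt(2))), 1000
  )
  expect_lt(abs(snr_db_between(tone, noise)), 0.2)
  double <- sampled_signal(2 * tone$value, 1000)
  expect_equal(snr_db_between(double, noise) - snr_db_between(tone, noise),
               20 * log10(2), tolerance = 1e-2)
  zero <- sampled_signal(rep(0, 100000), 1000)
  expect_error(snr_db_between(tone, zero), "zero-power")
})

test_that("glance on a removal report is a tidy one-row summary", {
  eeg <- synth_eeg_surrogate(200, 1000, rms = 30, seed = 6)
  tone <- generate_sinusoid(harmonic_params(50, 50.05), 200, 1000)
  g <- glance(remove_pla(compose_signals(eeg, tone), "dsca",
                         search_band = c(45, 65), reference = eeg))
  expect_s3_class(g, "tbl_df")
  expect_equal(nrow(g), 1)
  expect_equal(g$method, "dsca")
  expect_lt(abs(g$frequency - 50.05), 0.01)
  gn <- glance(remove_pla(compose_signals(eeg, tone), "notch"))
  expect_true(is.na(gn$amplitude) && is.na(gn$correlation_vs_reference))
})
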