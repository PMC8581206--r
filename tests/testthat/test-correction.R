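make_pair <- function(y_l, y_r, f_l = 250, delta_f = 1,
                      phase_l = 0, phase_r = 0) {
  out <- tibble::tibble(
    side = c("left", "right"),
    frequency = c(f_l, f_l + delta_f),
    amplitude = c(y_l, y_r),
    phase = c(phase_l, phase_r)
  )
  attr(out, "delta_f") <- delta_f
  attr(out, "source_n") <- 1000L
  class(out) <- c("bssl_pair", class(out))
  out
}

test_that("the ratio correction maps line amplitudes to the normalized shift", {
  # the worked example's printed value
  expect_equal(round(rbsc_delta_k(make_pair(0.996, 0.052)), 2), 0.05)
  # on-grid and symmetric-leakage limits
  expect_equal(rbsc_delta_k(make_pair(1, 0)), 0)
  expect_equal(rbsc_delta_k(make_pair(0.7, 0.7)), 0.5)
  expect_error(rbsc_delta_k(make_pair(0, 0)), "zero")
})

test_that("rbsc_estimate applies the sinc amplitude correction with its limit", {
  on_grid <- rbsc_estimate(make_pair(2.5, 0, phase_l = 0.4))
  expect_equal(on_grid$amplitude, 2.5)
  expect_equal(on_grid$frequency, 250)
  expect_equal(on_grid$phase, 0.4)

  half <- rbsc_estimate(make_pair(1, 1))
  expect_equal(half$amplitude, pi / 2) # pi * 0.5 / sin(pi * 0.5)
  expect_equal(half$frequency, 250.5)
})

test_that("the full single-round estimator recovers the worked example at printed precision", {
  fit <- rbsc_fit(worked_example_tone())
  expect_equal(round(fit$final$amplitude, 2), 1)
  expect_equal(round(fit$final$frequency, 2), 250.05)
  expect_equal(round(fit$final$phase, 2), 0)
})

test_that("noise-free tones are recovered almost exactly by both estimators", {
  cases <- random_tones(60, f_range = c(100, 400), seed = 31)
  for (i in seq_len(nrow(cases))) {
    truth <- harmonic_params(cases$amplitude[i], cases$frequency[i],
                             cases$phase[i])
    sig <- generate_sinusoid(truth, 1000, 1000)
    for (method in c("rbsc", "dsca")) {
      est <- estimate_pla(sig, method = method)$final
      # frequency accuracy is limited by the negative-frequency image, whose
      # worst-case contribution near the 100 Hz edge of the draw is ~1.3e-3
      # bins; 2e-3 * delta_f bounds it with margin
      expect_lt(abs(est$frequency - truth$frequency), 2e-3)
      expect_lt(abs(est$amplitude - truth$amplitude) / truth$amplitude, 1e-2)
      expect_lt(abs(wrap_phase(est$phase - truth$phase)), 2e-2)
    }
  }
})

test_that("the dual-step fit re-centres round 2 at half a bin and merges per plan", {
  fit <- dsca_estimate(worked_example_tone())
  expect_equal(nrow(fit$rounds), 2)
  # round-2 pair straddles the round-1 frequency by exactly half a bin
  expect_equal(fit$rounds$f_left[2], fit$rounds$frequency[1] - 0.5)
  expect_equal(fit$rounds$f_right[2], fit$rounds$frequency[1] + 0.5)
  expect_true(fit$rounds$delta_k[2] > 0.4 && fit$rounds$delta_k[2] < 0.6)
  # merge rule: amplitude from round 1, frequency and phase from round 2
  expect_identical(fit$final$amplitude, fit$rounds$amplitude[1])
  expect_identical(fit$final$frequency, fit$rounds$frequency[2])
  expect_identical(fit$final$phase, fit$rounds$phase[2])

  # on-grid tone: round 2 straddles the truth symmetrically
  on_grid <- dsca_estimate(generate_sinusoid(harmonic_params(1, 250), 1000, 1000))
  expect_lt(abs(on_grid$rounds$delta_k[2] - 0.5), 1e-3)
  expect_lt(abs(on_grid$final$frequency - 250), 1e-6)
})

test_that("noise-free estimates match the brute-force least-squares oracle", {
  cases <- random_tones(8, f_range = c(100, 400), seed = 13)
  for (i in seq_len(nrow(cases))) {
    truth <- harmonic_params(cases$amplitude[i], cases$frequency[i],
                             cases$phase[i])
    sig <- generate_sinusoid(truth, 1000, 1000)
    oracle <- oracle_sinusoid_fit(sig$value, 1000)
    est <- dsca_estimate(sig)$final
    expect_lt(abs(est$frequency - oracle$frequency), 1e-3)
    expect_lt(abs(est$amplitude - oracle$amplitude) / oracle$amplitude, 1e-2)
    expect_lt(abs(wrap_phase(est$phase - oracle$phase)), 2e-2)
  }
})

test_that("the exact phase-slope option changes the phase by O(pi*dk/N)", {
  sig <- worked_example_tone()
  nominal <- dsca_estimate(sig, phase_slope = "nominal")$final
  exact <- dsca_estimate(sig, phase_slope = "exact")$final
  expect_false(identical(nominal$phase, exact$phase))
  expect_lt(abs(nominal$phase - exact$phase), pi / 1000)
  expect_equal(nominal$frequency, exact$frequency)
})

test_that("under noise the dual step is no worse than the single round at small delta_k", {
  tb <- run_monte_carlo(0, 0.05, trials = 200, master_seed = 17)
  rmse <- tidyr::pivot_wider(tb[, c("method", "rmse_frequency")],
                             names_from = "method",
                             values_from = "rmse_frequency")
  expect_lte(rmse$dsca, rmse$rbsc)
})

test_that("returned phases always lie in (-pi, pi]", {
  cases <- random_tones(20, seed = 55)
  for (i in seq_len(nrow(cases))) {
    sig <- add_gaussian_noise(
      generate_sinusoid(harmonic_params(cases$amplitude[i], cases$frequency[i],
                                        cases$phase[i]), 1000, 1000),
      snr_db = 10, seed = i
    )
    fit <- dsca_estimate(sig)
    expect_true(all(fit$rounds$phase > -pi & fit$rounds$phase <= pi))
    expect_true(fit$final$phase > -pi && fit$final$phase <= pi)
  }
})
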