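# Independent brute-force oracle for single-sinusoid fits: coarse peak from a
# 128x zero-padded periodogram, then residual-sum-of-squares minimization on a
# grid at 1e-4 * delta_f resolution around it, each grid point solved by exact
# two-basis least squares. Shares no code with the ratio-correction path.
oracle_sinusoid_fit <- function(values, fs, band = NULL) {
  n <- length(values)
  df <- fs / n
  pad <- 128L
  big <- stats::fft(c(values, numeric(n * (pad - 1L))))
  freqs <- (seq_len(n * pad) - 1) * fs / (n * pad)
  keep <- freqs > 0 & freqs < fs / 2
  if (!is.null(band)) keep <- keep & freqs >= band[1] & freqs <= band[2]
  f0 <- freqs[keep][which.max(Mod(big[keep]))]
  grid <- seq(f0 - 2 * df / pad, f0 + 2 * df / pad, by = 1e-4 * df)
  idx <- 0:(n - 1)
  ls_fit <- function(f) {
    basis <- cbind(cos(2 * pi * f * idx / fs), sin(2 * pi * f * idx / fs))
    beta <- qr.solve(basis, values)
    list(rss = sum((values - basis %*% beta)^2), beta = beta)
  }
  rss <- vapply(grid, function(f) ls_fit(f)$rss, numeric(1))
  f_best <- grid[which.min(rss)]
  beta <- ls_fit(f_best)$beta
  list(
    amplitude = sqrt(sum(beta^2)),
    frequency = f_best,
    phase = atan2(-beta[2], beta[1])
  )
}
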