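# Minimal IIR building blocks. No filter-design package is assumed; the two
# biquads used here (Butterworth low/high-pass sections and the constrained
# notch) follow the standard bilinear-transform cookbook forms.

# Direct-form-I second-order section. a[1] need not be 1.
biquad_filter <- function(x, b, a) {
  b <- b / a[1]
  a <- a / a[1]
  n <- length(x)
  y <- numeric(n)
  x1 <- 0; x2 <- 0; y1 <- 0; y2 <- 0
  for (i in seq_len(n)) {
    y[i] <- b[1] * x[i] + b[2] * x1 + b[3] * x2 - a[2] * y1 - a[3] * y2
    x2 <- x1; x1 <- x[i]
    y2 <- y1; y1 <- y[i]
  }
  y
}

# Second-order Butterworth low/high-pass coefficients (Q = 1/sqrt(2)).
butter2_coef <- function(fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  w0 <- 2 * pi * fc / fs
  cw <- cos(w0)
  alpha <- sin(w0) / (2 * (1 / sqrt(2)))
  b <- if (type == "low") {
    c((1 - cw) / 2, 1 - cw, (1 - cw) / 2)
  } else {
    c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2)
  }
  a <- c(1 + alpha, -2 * cw, 1 - alpha)
  list(b = b, a = a)
}

# Second-order IIR notch with unit gain at DC and Nyquist.
notch_coef <- function(center_hz, fs, q) {
  w0 <- 2 * pi * center_hz / fs
  alpha <- sin(w0) / (2 * q)
  list(
    b = c(1, -2 * cos(w0), 1),
    a = c(1 + alpha, -2 * cos(w0), 1 - alpha)
  )
}
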