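# Writes a minimal single-record 16-bit EDF file for round-trip tests.
# Synthetic fixture, built at test time in a temporary directory.
write_synthetic_edf <- function(path, values, fs, label = "EEG Fpz") {
  n <- length(values)
  dig_min <- -32768
  dig_max <- 32767
  span <- signif(max(abs(values)) * 1.05 + 1e-9, 5)
  phys_min <- -span
  phys_max <- span
  digital <- as.integer(round((values - phys_min) /
                                (phys_max - phys_min) *
                                (dig_max - dig_min) + dig_min))
  field <- function(x, width) {
    s <- format(x, trim = TRUE, scientific = FALSE)
    s <- substr(s, 1, width)
    sprintf("%-*s", width, s)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  put <- function(s) writeBin(charToRaw(s), con)
  put(field("0", 8))                     # version
  put(field("synthetic patient", 80))
  put(field("synthetic recording", 80))
  put(field("01.01.26", 8))
  put(field("00.00.00", 8))
  put(field(256 + 256, 8))               # header bytes, 1 signal
  put(field("", 44))
  put(field(1, 8))                       # number of data records
  put(field(format(n / fs, digits = 10), 8)) # record duration, seconds
  put(field(1, 4))                       # number of signals
  put(field(label, 16))
  put(field("synthetic", 80))
  put(field("uV", 8))
  put(field(format(phys_min, digits = 7), 8))
  put(field(format(phys_max, digits = 7), 8))
  put(field(dig_min, 8))
  put(field(dig_max, 8))
  put(field("none", 80))
  put(field(n, 8))                       # samples per record
  put(field("", 32))
  writeBin(digital, con, size = 2, endian = "little")
  invisible(path)
}
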