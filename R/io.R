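#' Read a delimited-text channel file
#'
#' The channel dialect is deliberately minimal: UTF-8 text, `#`-prefixed
#' header lines of the form `# key=value` (the key `fs_hz` is required), then
#' one sample per line with `.` as the decimal separator.
#'
#' @param path Path to the channel file.
#' @return A [sampled_signal()].
#' @export
read_channel_text <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  is_header <- grepl("^\\s*#", lines)
  headers <- list()
  for (i in which(is_header)) {
    body <- sub("^\\s*#\\s*", "", lines[i])
    if (grepl("=", body, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", body))
      headers[[key]] <- trimws(sub("^[^=]*=", "", body))
    }
  }
  if (is.null(headers$fs_hz)) {
    abort(sprintf("%s: missing required header `# fs_hz=<value>`.", path))
  }
  fs <- suppressWarnings(as.numeric(headers$fs_hz))
  if (is.na(fs) || fs <= 0) {
    header_line <- which(is_header & grepl("fs_hz", lines))[1]
    abort(sprintf("%s:%d: invalid fs_hz value `%s`.", path, header_line,
                  headers$fs_hz))
  }
  data_idx <- which(!is_header & nzchar(trimws(lines)))
  values <- suppressWarnings(as.numeric(trimws(lines[data_idx])))
  if (anyNA(values)) {
    bad <- data_idx[which(is.na(values))[1]]
    abort(sprintf("%s:%d: non-numeric sample `%s`.", path, bad,
                  trimws(lines[bad])))
  }
  if (length(values) < 2) {
    abort(sprintf("%s: a channel needs at least 2 samples, found %d.",
                  path, length(values)))
  }
  sig <- sampled_signal(values, fs)
  if (!is.null(headers$label)) attr(sig, "label") <- headers$label
  sig
}

#' Write a signal as a delimited-text channel file
#'
#' Emits the dialect read by [read_channel_text()]: first line exactly
#' `# fs_hz=<value>`, then one sample per line at 15 significant digits.
#'
#' @param signal A [sampled_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_channel_text <- function(signal, path) {
  if (!is.character(path) || length(path) != 1 || !nzchar(path)) {
    abort("`path` must be a non-empty file path.")
  }
  signal <- as_sampled_signal(signal)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.15g", sample_rate(signal)), con)
  writeLines(formatC(signal$value, digits = 15, format = "g"), con)
  invisible(path)
}

#' Read one channel from an EDF recording
#'
#' Minimal pure-R reader for European Data Format (EDF) files: parses the
#' 256-byte ASCII header plus per-signal header blocks, decodes the 16-bit
#' little-endian data records of the requested channel and applies the
#' physical calibration. The sampling rate is taken from the header
#' (samples-per-record / record duration), never guessed. Read-only; EDF+
#' annotation channels are not interpreted.
#'
#' @param path Path to an EDF file.
#' @param channel Channel label (matched after trimming whitespace) or a
#'   1-based channel index.
#' @return A [sampled_signal()] with a `label` attribute.
#' @export
read_edf_channel <- function(path, channel = 1L) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  con <- file(path, open = "rb")
  on.exit(close(con))
  ascii <- function(nchars) trimws(rawToChar(readBin(con, "raw", nchars)))
  version <- ascii(8)
  if (!identical(version, "0")) {
    abort(sprintf("%s does not look like an EDF file (version field `%s`).",
                  path, version))
  }
  ascii(80); ascii(80); ascii(8); ascii(8) # patient, recording, date, time
  ascii(8)                                 # header length
  ascii(44)                                # reserved
  n_records <- as.integer(ascii(8))
  record_dur <- as.numeric(ascii(8))
  ns <- as.integer(ascii(4))
  if (is.na(ns) || ns < 1) abort(sprintf("%s: invalid signal count.", path))
  labels <- vapply(seq_len(ns), function(i) ascii(16), "")
  for (i in seq_len(ns)) ascii(80) # transducer
  for (i in seq_len(ns)) ascii(8)  # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(ascii(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(ascii(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(ascii(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(ascii(8)), 0)
  for (i in seq_len(ns)) ascii(80) # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(ascii(8)), 0L)
  for (i in seq_len(ns)) ascii(32) # reserved

  idx <- if (is.numeric(channel)) {
    as.integer(channel)
  } else {
    match(trimws(channel), labels)
  }
  if (is.na(idx) || idx < 1 || idx > ns) {
    abort(sprintf("channel `%s` not found in %s; available: %s",
                  as.character(channel), path,
                  paste(labels, collapse = ", ")))
  }
  gain <- (phys_max[idx] - phys_min[idx]) / (dig_max[idx] - dig_min[idx])
  values <- numeric(n_records * spr[idx])
  pos <- 0L
  for (rec in seq_len(n_records)) {
    for (sig in seq_len(ns)) {
      raw16 <- readBin(con, "integer", n = spr[sig], size = 2,
                       endian = "little", signed = TRUE)
      if (sig == idx) {
        values[(pos + 1):(pos + spr[sig])] <- raw16
        if (sig == idx) pos <- pos + spr[sig]
      }
    }
  }
  phys <- (values - dig_min[idx]) * gain + phys_min[idx]
  fs <- spr[idx] / record_dur
  sig <- sampled_signal(phys, fs)
  attr(sig, "label") <- labels[idx]
  sig
}
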