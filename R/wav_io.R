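#' Waveform container
#'
#' A `call_wave` holds one call segment's audio: a numeric sample vector in
#' `[-1, 1]` and a sampling rate in Hz.
#'
#' @param samples Numeric vector of audio samples.
#' @param rate Sampling rate in samples per second (> 0).
#' @return An object of class `call_wave` with elements `samples` and `rate`.
#' @export
call_wave <- function(samples, rate) {
  if (!is.numeric(samples)) stop_validation("samples must be numeric")
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate <= 0) {
    stop_validation("rate must be a single positive number")
  }
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "call_wave")
}

#' @export
print.call_wave <- function(x, ...) {
  cat(sprintf("<call_wave: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' @export
length.call_wave <- function(x) length(x$samples)

read_u32 <- function(con) readBin(con, "integer", 1L, size = 4L, endian = "little")
read_u16 <- function(con) readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                                  endian = "little")

#' Read a mono RIFF WAV file
#'
#' Reads PCM (8/16/24-bit integer or 32-bit IEEE float) WAV audio. Multichannel
#' files are reduced to their first channel. Samples are scaled to `[-1, 1]`
#' and the original sampling rate is preserved.
#'
#' @param path Path to a `.wav` file.
#' @return A [call_wave()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(riff, "RIFF")) stop_validation("not a RIFF file: ", path)
  read_u32(con)
  wave <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(wave, "WAVE")) stop_validation("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id_raw <- readBin(con, "raw", 4L)
    if (length(id_raw) < 4L) break
    id <- rawToChar(id_raw)
    size <- read_u32(con)
    if (is.na(size) || size < 0) stop_validation("corrupt chunk in ", path)
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = read_u16(con),
        channels = read_u16(con),
        rate = read_u32(con),
        byte_rate = read_u32(con),
        block_align = read_u16(con),
        bits = read_u16(con)
      )
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (length(data_raw) < size) stop_validation("truncated data chunk in ", path)
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2L == 1L) readBin(con, "raw", 1L)  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop_validation("no fmt chunk in ", path)
  if (is.null(data_raw) || length(data_raw) == 0L) {
    stop_validation("zero-length audio in ", path)
  }

  bits <- fmt$bits
  n_ch <- max(1L, fmt$channels)
  if (fmt$format == 1L && bits == 16L) {
    n <- length(data_raw) %/% 2L
    x <- readBin(data_raw, "integer", n, size = 2L, endian = "little") / 32768
  } else if (fmt$format == 1L && bits == 24L) {
    n <- length(data_raw) %/% 3L
    b <- as.integer(data_raw[seq_len(n * 3L)])
    v <- b[seq(1L, by = 3L, length.out = n)] +
      256L * b[seq(2L, by = 3L, length.out = n)] +
      65536L * b[seq(3L, by = 3L, length.out = n)]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else if (fmt$format == 1L && bits == 8L) {
    x <- (as.integer(data_raw) - 128L) / 128
  } else if (fmt$format == 3L && bits == 32L) {
    n <- length(data_raw) %/% 4L
    x <- readBin(data_raw, "numeric", n, size = 4L, endian = "little")
  } else {
    stop_validation("unsupported WAV encoding (format ", fmt$format,
                    ", ", bits, " bit)")
  }
  if (n_ch > 1L) x <- x[seq(1L, length(x), by = n_ch)]
  if (length(x) == 0L) stop_validation("zero-length audio in ", path)
  call_wave(x, fmt$rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' @param w A [call_wave()]. Samples outside `[-1, 1]` are clipped.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "call_wave"))
  x <- pmin(1, pmax(-1, w$samples))
  v <- pmin(32767L, pmax(-32768L, as.integer(round(x * 32768))))
  n_bytes <- length(v) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")          # PCM
  writeBin(1L, con, size = 2L, endian = "little")          # mono
  writeBin(as.integer(w$rate), con, size = 4L, endian = "little")
  writeBin(as.integer(w$rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")          # block align
  writeBin(16L, con, size = 2L, endian = "little")         # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4L, endian = "little")
  writeBin(v, con, size = 2L, endian = "little")
  invisible(path)
}
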