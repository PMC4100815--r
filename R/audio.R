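#' Call types of the female western gorilla repertoire
#'
#' The eight discrete call types analysed by the pipeline: three "repeated"
#' types (threat grunt, copulation grunt, hoot series) consist of sequences
#' of similar call segments; the others are given as single segments.
#'
#' @return Character vector of the eight call-type tokens.
#' @export
call_types <- function() {
  c("single_grunt", "double_grunt", "grumble", "threat_grunt",
    "copulation_grunt", "hum", "hoot_series", "scream")
}

#' Call types whose vocalizations repeat similar call segments in sequences
#' @return Character vector, subset of [call_types()].
#' @export
repeated_call_types <- function() {
  c("threat_grunt", "copulation_grunt", "hoot_series")
}

#' Default analysis sampling rate per call type
#'
#' Calls are analysed after downsampling to one of three rates chosen by the
#' call's frequency range: 22050 Hz for high-frequency loud calls, 11025 Hz
#' for harmonically rich mid-range calls, 4000 Hz for low-pitched grunts.
#' The assignment is a package default and can be overridden wherever a rate
#' map is accepted.
#'
#' @return Named numeric vector mapping each call type to a rate in Hz.
#' @export
default_band_rates <- function() {
  c(single_grunt = 4000, double_grunt = 4000, grumble = 4000,
    threat_grunt = 11025, copulation_grunt = 4000, hum = 4000,
    hoot_series = 11025, scream = 22050)
}

#' Analysis sampling rate for a call type
#'
#' @param call_type One of [call_types()] (or a name present in `rates`).
#' @param rates Named call-type to rate map; values must be one of
#'   22050, 11025 or 4000 Hz.
#' @return The analysis rate in Hz.
#' @export
select_band_rate <- function(call_type, rates = default_band_rates()) {
  if (!all(rates %in% c(22050, 11025, 4000))) {
    stop_validation("rates must map call types to 22050, 11025 or 4000 Hz")
  }
  if (length(call_type) != 1L || !call_type %in% names(rates)) {
    stop_validation("unknown call type: ", paste(call_type, collapse = ", "))
  }
  unname(rates[[call_type]])
}

#' Downsample a waveform
#'
#' Polyphase resampling (anti-aliased) to a lower target rate. Upsampling is
#' refused: analysis rates are always at or below the recording rate.
#'
#' @param w A [call_wave()].
#' @param target Target rate in Hz, `<= w$rate`.
#' @return A [call_wave()] at `target` Hz.
#' @export
resample_wave <- function(w, target) {
  stopifnot(inherits(w, "call_wave"))
  if (target > w$rate) {
    stop_validation("no upsampling: target ", target, " > rate ", w$rate)
  }
  if (target == w$rate) return(w)
  g <- gcd_int(round(target), round(w$rate))
  p <- round(target) / g
  q <- round(w$rate) / g
  y <- signal::resample(w$samples, p, q)
  call_wave(as.numeric(y), target)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

spec_window <- function(window, frame_len) {
  if (is.function(window)) return(window(frame_len))
  if (is.numeric(window)) {
    if (length(window) != frame_len) {
      stop_validation("numeric window must have length ", frame_len)
    }
    return(window)
  }
  switch(match.arg(window, c("hamming", "rectangular")),
         hamming = signal::hamming(frame_len),
         rectangular = rep(1, frame_len))
}

#' Short-time spectrogram of a call segment
#'
#' Frames of `frame_len` samples are windowed, zero-padded to `fft_len`
#' points and Fourier transformed. With the defaults (256-sample frames
#' zero-padded to a 1024-point FFT, 93 % overlap) the hop is
#' `round(256 * 0.07) = 18` samples, the frame count is
#' `floor((N - 256) / 18) + 1` and the bin spacing is `rate / 1024`.
#'
#' @param w A [call_wave()] with at least `frame_len` samples.
#' @param frame_len Samples per analysis frame.
#' @param fft_len FFT length (frames are zero-padded up to it).
#' @param overlap Fractional frame overlap in `[0, 1)`.
#' @param window `"hamming"` (default), `"rectangular"`, a numeric vector of
#'   length `frame_len`, or a function of the frame length. The window
#'   choice affects tonality/noisiness estimates; see the package vignette.
#' @return An object of class `call_spec`: list with `mag` (frames x bins
#'   magnitude matrix, non-negative), `bin_hz`, `frame_times` (s, frame
#'   centres), `rate`, `n_samples` and `settings`.
#' @export
spectrogram <- function(w, frame_len = 256L, fft_len = 1024L,
                        overlap = 0.93, window = "hamming") {
  stopifnot(inherits(w, "call_wave"))
  n <- length(w$samples)
  if (n < frame_len) {
    stop_validation("need at least ", frame_len, " samples, got ", n)
  }
  if (fft_len < frame_len) stop_validation("fft_len must be >= frame_len")
  hop <- max(1L, as.integer(round(frame_len * (1 - overlap))))
  n_frames <- (n - frame_len) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  win <- spec_window(window, frame_len)

  idx <- outer(seq_len(frame_len), starts, `+`)
  frames <- matrix(w$samples[idx], nrow = frame_len) * win
  padded <- rbind(frames, matrix(0, nrow = fft_len - frame_len, ncol = n_frames))
  n_bins <- fft_len %/% 2L + 1L
  mag <- t(Mod(stats::mvfft(padded))[seq_len(n_bins), , drop = FALSE])

  structure(list(
    mag = mag,
    bin_hz = w$rate / fft_len,
    frame_times = (starts + frame_len / 2) / w$rate,
    rate = w$rate,
    n_samples = n,
    settings = list(frame_len = frame_len, fft_len = fft_len,
                    overlap = overlap, hop = hop,
                    window = if (is.character(window)) window else "custom")
  ), class = "call_spec")
}

#' @export
print.call_spec <- function(x, ...) {
  cat(sprintf("<call_spec: %d frames x %d bins, bin %.3f Hz, %.1f ms>\n",
              nrow(x$mag), ncol(x$mag), x$bin_hz,
              1000 * x$n_samples / x$rate))
  invisible(x)
}
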