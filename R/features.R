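#' Names of the twenty acoustic parameters
#'
#' Time, frequency, energy, relative-amplitude and tonality parameters
#' measured per call segment: segment duration; energy-quartile frequencies
#' (dfa1*, dfa2*); first dominant frequency band statistics (df1*), band
#' count and spacing (diffreq, diffmean, ampratio1); first spectral peak
#' (fp1*); frequency range (ranmean); peak frequency (pf*); and the
#' percentages of noisy and tonal time frames.
#'
#' @return Character vector of length 20 (column order of feature tables).
#' @export
feature_names <- function() {
  c("duration",
    "dfa1mean", "dfa1maloc", "dfa2mean", "dfa2maloc",
    "df1max", "df1min", "df1mean",
    "diffmean", "diffreq", "ampratio1",
    "fp1max", "fp1mean", "fp1amean",
    "ranmean",
    "pfmax", "pfmin", "pfmean",
    "noise", "tonality")
}

#' Tuning options for feature extraction
#'
#' @param band_threshold_db Dominant-band threshold in dB relative to the
#'   frame maximum (must be negative). A spectral bin belongs to a dominant
#'   band when its magnitude is within this many dB of the frame peak. This
#'   is the single most consequential free parameter of the extraction; see
#'   the vignette.
#' @param tonal_cut,noisy_cut Spectral-flatness cut points: a frame is tonal
#'   when its flatness is `<= tonal_cut`, noisy when `>= noisy_cut`, and
#'   "neither" in between (so noise + tonality need not sum to 100).
#' @param flatness_block Number of adjacent power-spectrum bins averaged
#'   before computing spectral flatness (variance reduction of the
#'   periodogram; 16 bins makes sampled white noise read as flat).
#' @return A list of class `feature_options`.
#' @export
feature_options <- function(band_threshold_db = -24, tonal_cut = 0.3,
                            noisy_cut = 0.7, flatness_block = 16L) {
  if (band_threshold_db >= 0) {
    stop_validation("band_threshold_db must be negative (relative to peak)")
  }
  if (!(tonal_cut < noisy_cut)) stop_validation("tonal_cut must be < noisy_cut")
  structure(list(band_threshold_db = band_threshold_db,
                 tonal_cut = tonal_cut, noisy_cut = noisy_cut,
                 flatness_block = as.integer(flatness_block)),
            class = "feature_options")
}

#' Frequency at which a cumulative energy quantile is reached
#'
#' The smallest bin-centre frequency at which the cumulative squared
#' magnitude of one frame's spectrum reaches `q` of the total.
#'
#' @param magnitudes Non-negative magnitude vector for one frame (bin 1 = 0 Hz).
#' @param bin_hz Frequency spacing between bins.
#' @param q Energy fraction, typically 0.25 (first quartile) or 0.5 (second).
#' @return Frequency in Hz, or `NA` for a zero-energy frame.
#' @export
energy_quartile_frequency <- function(magnitudes, bin_hz, q) {
  if (q <= 0 || q > 1) stop_validation("q must be in (0, 1]")
  e <- magnitudes^2
  tot <- sum(e)
  if (tot <= 0) return(NA_real_)
  (which(cumsum(e) >= q * tot)[1L] - 1L) * bin_hz
}

#' Dominant frequency bands of one frame
#'
#' Maximal runs of contiguous bins whose magnitude is within
#' `threshold_db` dB of the frame maximum. Each band is reported at its peak
#' bin; bands are ordered by ascending frequency, so the "first" band is the
#' lowest-frequency one.
#'
#' @inheritParams energy_quartile_frequency
#' @param threshold_db Negative threshold in dB relative to the frame maximum.
#' @return Data frame with one row per band: `freq` (peak bin, Hz), `amp`
#'   (peak magnitude), `low`, `high` (band edge frequencies, Hz). Zero rows
#'   for a silent frame.
#' @export
dominant_bands <- function(magnitudes, bin_hz, threshold_db = -24) {
  if (threshold_db >= 0) stop_validation("threshold_db must be negative")
  empty <- data.frame(freq = numeric(0), amp = numeric(0),
                      low = numeric(0), high = numeric(0))
  m <- max(magnitudes)
  if (m <= 0) return(empty)
  above <- magnitudes >= m * 10^(threshold_db / 20)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  if (!length(ok)) return(empty)
  bands <- lapply(ok, function(k) {
    i <- starts[k]:ends[k]
    pk <- i[which.max(magnitudes[i])]
    c(freq = (pk - 1L) * bin_hz, amp = magnitudes[pk],
      low = (i[1L] - 1L) * bin_hz, high = (i[length(i)] - 1L) * bin_hz)
  })
  out <- as.data.frame(do.call(rbind, bands))
  out[order(out$freq), , drop = FALSE]
}

# Vectorized band summary for the extraction loop: peak frequency and
# amplitude per band (ascending frequency) plus the overall above-threshold
# frequency span. Same definition as dominant_bands, no data.frame cost.
band_summary <- function(magnitudes, bin_hz, threshold_db) {
  m <- max(magnitudes)
  above <- magnitudes >= m * 10^(threshold_db / 20)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  freqs <- amps <- numeric(length(ok))
  for (u in seq_along(ok)) {
    i <- starts[ok[u]]:ends[ok[u]]
    pk <- i[which.max(magnitudes[i])]
    freqs[u] <- (pk - 1L) * bin_hz
    amps[u] <- magnitudes[pk]
  }
  list(freq = freqs, amp = amps,
       span = (ends[ok[length(ok)]] - starts[ok[1L]]) * bin_hz)
}

# Spectral flatness (Wiener entropy) of one frame's power spectrum,
# computed on a block-averaged periodogram: geometric / arithmetic mean,
# 1 for a flat spectrum, near 0 for a line spectrum.
spectral_flatness <- function(magnitudes, block = 16L) {
  p <- magnitudes^2
  n_blk <- length(p) %/% block
  if (n_blk >= 2L) {
    p <- colMeans(matrix(p[seq_len(n_blk * block)], nrow = block))
  }
  p <- p / sum(p)
  exp(mean(log(pmax(p, .Machine$double.xmin)))) / mean(p)
}

#' Classify a frame as tonal, noisy or neither
#'
#' Tonality is judged by spectral flatness (Wiener entropy): concentrated
#' (line-like) spectra are tonal, flat spectra are noisy, intermediate
#' frames are neither.
#'
#' @inheritParams energy_quartile_frequency
#' @param opts A [feature_options()] supplying the flatness cut points.
#' @return One of `"tonal"`, `"noisy"`, `"neither"`.
#' @export
frame_tonality <- function(magnitudes, opts = feature_options()) {
  if (sum(magnitudes^2) <= 0) stop_validation("zero-energy frame")
  f <- spectral_flatness(magnitudes, opts$flatness_block)
  if (f <= opts$tonal_cut) "tonal" else if (f >= opts$noisy_cut) "noisy" else "neither"
}

# Lowest-frequency local spectral maximum at or above the band threshold.
# Ties and plateaus resolve toward the lower frequency.
first_peak <- function(magnitudes, threshold_db) {
  m <- max(magnitudes)
  if (m <= 0) return(NULL)
  thr <- m * 10^(threshold_db / 20)
  n <- length(magnitudes)
  left <- c(-Inf, magnitudes[-n])
  right <- c(magnitudes[-1L], -Inf)
  is_peak <- magnitudes >= thr & magnitudes >= left & magnitudes > right
  # plateau: magnitudes > right fails at internal plateau starts followed by
  # equal values; accept bins strictly greater than the next differing value
  if (!any(is_peak)) is_peak <- magnitudes >= thr & magnitudes >= left & magnitudes >= right
  i <- which(is_peak)[1L]
  if (is.na(i)) return(NULL)
  list(index = i, rel_amp = magnitudes[i] / m)
}

#' Extract the twenty acoustic parameters from a spectrogram
#'
#' Per-frame quantities (energy-quartile frequencies, dominant bands, peak
#' frequency, first spectral peak, frequency range, tonal/noisy flag) are
#' computed for every non-silent frame and aggregated over the segment.
#' All thresholds are relative to the frame maximum, so every parameter is
#' invariant to amplitude scaling of the waveform.
#'
#' Frames with zero energy are excluded from all aggregations. "Location"
#' parameters (`dfa1maloc`, `dfa2maloc`) are the relative temporal position
#' in `[0, 1]` of the frame attaining the maximum quartile frequency
#' (0.5 for a one-frame segment). When no frame shows two or more dominant
#' bands, `diffmean` and `ampratio1` are `NA` and are handled by listwise
#' deletion before discriminant analysis.
#'
#' @param spec A `call_spec` from [spectrogram()].
#' @param opts A [feature_options()].
#' @return Named numeric vector with the entries of [feature_names()].
#' @export
extract_features <- function(spec, opts = feature_options()) {
  stopifnot(inherits(spec, "call_spec"))
  mag <- spec$mag
  bin_hz <- spec$bin_hz
  n_frames <- nrow(mag)
  energy <- rowSums(mag^2)
  live <- which(energy > 0)
  if (!length(live)) stop_validation("all-silent segment")

  thr_db <- opts$band_threshold_db
  k <- length(live)
  dfa1 <- dfa2 <- pf <- fp1f <- fp1a <- ran <- nband <- rep(NA_real_, k)
  band1 <- band_diff <- band_ratio <- rep(NA_real_, k)
  flags <- character(k)

  for (j in seq_len(k)) {
    v <- mag[live[j], ]
    dfa1[j] <- energy_quartile_frequency(v, bin_hz, 0.25)
    dfa2[j] <- energy_quartile_frequency(v, bin_hz, 0.5)
    pf[j] <- (which.max(v) - 1L) * bin_hz
    b <- band_summary(v, bin_hz, thr_db)
    nband[j] <- length(b$freq)
    band1[j] <- b$freq[1L]
    if (nband[j] >= 2L) {
      band_diff[j] <- b$freq[2L] - b$freq[1L]
      band_ratio[j] <- b$amp[1L] / b$amp[2L]
    }
    ran[j] <- b$span
    p1 <- first_peak(v, thr_db)
    if (!is.null(p1)) {
      fp1f[j] <- (p1$index - 1L) * bin_hz
      fp1a[j] <- p1$rel_amp
    }
    flags[j] <- frame_tonality(v, opts)
  }

  rel_loc <- function(j_local) {
    if (n_frames == 1L) return(0.5)
    (live[j_local] - 1L) / (n_frames - 1L)
  }
  two_band <- which(nband >= 2L)

  c(duration = 1000 * spec$n_samples / spec$rate,
    dfa1mean = mean(dfa1), dfa1maloc = rel_loc(which.max(dfa1)),
    dfa2mean = mean(dfa2), dfa2maloc = rel_loc(which.max(dfa2)),
    df1max = max(band1), df1min = min(band1), df1mean = mean(band1),
    diffmean = if (length(two_band)) min(band_diff[two_band]) else NA_real_,
    diffreq = mean(nband),
    ampratio1 = if (length(two_band)) mean(band_ratio[two_band]) else NA_real_,
    fp1max = max(fp1f, na.rm = TRUE),
    fp1mean = mean(fp1f, na.rm = TRUE),
    fp1amean = mean(fp1a, na.rm = TRUE),
    ranmean = mean(ran, na.rm = TRUE),
    pfmax = max(pf), pfmin = min(pf), pfmean = mean(pf),
    noise = 100 * mean(flags == "noisy"),
    tonality = 100 * mean(flags == "tonal"))
}

#' Feature table for a set of call records
#'
#' Runs the audio pipeline per record: read WAV, downsample to the call
#' type's analysis rate, compute the spectrogram, extract the twenty
#' parameters.
#'
#' @param records Call-record table (see [call_records()]); `audio_path`
#'   must point to readable WAV files (relative paths are resolved against
#'   `audio_dir`).
#' @param audio_dir Optional directory prefix for relative `audio_path`s.
#' @param opts A [feature_options()].
#' @param rates Call-type to analysis-rate map (see [select_band_rate()]).
#' @param window Spectrogram window, see [spectrogram()].
#' @return Data frame with `segment_id`, `caller_id`, `call_type`,
#'   `sequence_id`, `timestamp`, then the twenty feature columns.
#' @export
features_from_audio <- function(records, audio_dir = NULL,
                                opts = feature_options(),
                                rates = default_band_rates(),
                                window = "hamming") {
  records <- call_records(records)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    path <- records$audio_path[i]
    if (!is.null(audio_dir) && !file.exists(path)) {
      path <- file.path(audio_dir, path)
    }
    w <- read_wav(path)
    target <- select_band_rate(records$call_type[i], rates)
    if (target < w$rate) w <- resample_wave(w, target)
    extract_features(spectrogram(w, window = window), opts)
  })
  cbind(records[c("segment_id", "caller_id", "call_type",
                  "sequence_id", "timestamp")],
        as.data.frame(do.call(rbind, rows)))
}
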