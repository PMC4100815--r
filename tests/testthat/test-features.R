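test_that("energy-quartile frequency follows the cumulative-sum definition", {
  bin_hz <- 1
  # all energy in one bin
  m <- rep(0, 2001); m[1001] <- 3
  expect_equal(energy_quartile_frequency(m, bin_hz, 0.25), 1000)
  expect_equal(energy_quartile_frequency(m, bin_hz, 0.5), 1000)
  # flat magnitude over bins 0..F: quartile frequency is q*F within one bin
  F_bins <- 800
  m2 <- rep(1, F_bins + 1)
  expect_lte(abs(energy_quartile_frequency(m2, bin_hz, 0.25) - 0.25 * F_bins), bin_hz)
  expect_lte(abs(energy_quartile_frequency(m2, bin_hz, 0.5) - 0.5 * F_bins), bin_hz)
  # two equal point masses: cumulative sum reaches both 0.25 and 0.5 at the first
  m3 <- rep(0, 2001); m3[c(501, 1501)] <- 1
  expect_equal(energy_quartile_frequency(m3, bin_hz, 0.25), 500)
  expect_equal(energy_quartile_frequency(m3, bin_hz, 0.5), 500)
  # zero-energy frame is not an error
  expect_true(is.na(energy_quartile_frequency(rep(0, 10), bin_hz, 0.25)))
  expect_error(energy_quartile_frequency(m, bin_hz, 0), "q must be")
})

test_that("dominant bands honour the relative amplitude threshold", {
  bin_hz <- 1
  tone <- rep(0, 2001); tone[1001] <- 1
  b <- dominant_bands(tone, bin_hz, -24)
  expect_equal(nrow(b), 1)
  expect_equal(b$freq, 1000)

  # -30 dB secondary tone is below a -24 dB threshold
  two <- rep(0, 2001); two[501] <- 1; two[1501] <- 10^(-30 / 20)
  expect_equal(nrow(dominant_bands(two, bin_hz, -24)), 1)

  # equal tones: two bands, spacing and amplitude ratio by construction
  eq <- rep(0, 2001); eq[c(501, 1501)] <- 1
  b2 <- dominant_bands(eq, bin_hz, -24)
  expect_equal(nrow(b2), 2)
  expect_equal(b2$freq[2] - b2$freq[1], 1000)
  expect_equal(b2$amp[1] / b2$amp[2], 1)

  expect_equal(nrow(dominant_bands(rep(0, 100), bin_hz, -24)), 0)
  expect_error(dominant_bands(tone, bin_hz, 6), "negative")
})

test_that("frame tonality separates tones, noise and mixtures", {
  w <- signal::hamming(256)
  t <- (0:255) / 22050
  tone <- frame_spectrum(sin(2 * pi * 1000 * t))
  expect_equal(frame_tonality(tone), "tonal")

  set.seed(5)
  noisy_ok <- vapply(1:20, function(i) {
    frame_tonality(frame_spectrum(rnorm(256)))
  }, character(1))
  expect_true(mean(noisy_ok == "noisy") >= 0.9)

  mixed <- vapply(1:20, function(i) {
    s <- sin(2 * pi * 1000 * t)
    frame_tonality(frame_spectrum(s + rnorm(256, sd = sd(s))))
  }, character(1))
  expect_true(mean(mixed == "neither") >= 0.9)
})

test_that("a pure tone yields the expected feature vector", {
  w <- tone_wave(1000, duration_s = 0.5, rate = 22050)
  s <- spectrogram(w)
  f <- extract_features(s)
  expect_equal(unname(f["duration"]), 500)
  expect_lte(abs(f[["pfmean"]] - 1000), s$bin_hz)
  expect_equal(f[["pfmax"]], f[["pfmean"]])
  expect_equal(f[["pfmin"]], f[["pfmean"]])
  expect_equal(unname(f["diffreq"]), 1)
  expect_equal(unname(f["tonality"]), 100)
  expect_equal(unname(f["noise"]), 0)
  expect_true(is.na(f[["diffmean"]]) && is.na(f[["ampratio1"]]))
  expect_named(f, feature_names())
})

test_that("a rising chirp is tracked across frames", {
  rate <- 11025
  n <- rate  # 1 s
  t <- (seq_len(n) - 1) / rate
  x <- sin(2 * pi * (500 * t + 0.5 * 1000 * t^2))  # 500 -> 1500 Hz
  s <- spectrogram(call_wave(x, rate))
  f <- extract_features(s)
  # ends are measured at frame centres, 128 samples in
  expect_lte(abs(f[["pfmin"]] - 500), 1000 * 128 / n + 2 * s$bin_hz)
  expect_lte(abs(f[["pfmax"]] - 1500), 1000 * 128 / n + 2 * s$bin_hz)
  expect_gte(f[["dfa2maloc"]], 0.9)
})

test_that("white noise reads as noisy with multiple bands", {
  set.seed(9)
  f <- extract_features(spectrogram(call_wave(rnorm(8000), 22050)))
  expect_gte(f[["noise"]], 90)
  expect_gt(f[["diffreq"]], 1)
})

test_that("feature order invariants hold on arbitrary segments", {
  set.seed(21)
  for (i in 1:8) {
    x <- rnorm(sample(500:4000, 1)) * (0.2 + runif(1))
    f <- extract_features(spectrogram(call_wave(x, 11025)))
    expect_lte(f[["df1min"]], f[["df1mean"]])
    expect_lte(f[["df1mean"]], f[["df1max"]])
    expect_lte(f[["pfmin"]], f[["pfmean"]])
    expect_lte(f[["pfmean"]], f[["pfmax"]])
    expect_lte(f[["noise"]] + f[["tonality"]], 100)
    expect_true(all(f[c("dfa1mean", "dfa2mean", "df1mean", "pfmean",
                        "fp1mean")] <= 11025 / 2))
  }
})

test_that("all twenty features are invariant to amplitude scaling", {
  set.seed(31)
  x <- rnorm(3000) + sin(2 * pi * 800 * (0:2999) / 11025)
  f1 <- extract_features(spectrogram(call_wave(x, 11025)))
  for (c_scale in c(0.05, 0.37, 4)) {
    f2 <- extract_features(spectrogram(call_wave(c_scale * x, 11025)))
    expect_equal(f2, f1, tolerance = 1e-12)
  }
})

test_that("time reversal mirrors location features and fixes the rest", {
  rate <- 11025
  n <- 256 + 18 * 150  # frames tile the signal exactly
  t <- (seq_len(n) - 1) / rate
  x <- sin(2 * pi * (400 * t + 0.5 * 2000 * t^2))
  f_fwd <- extract_features(spectrogram(call_wave(x, rate)))
  f_rev <- extract_features(spectrogram(call_wave(rev(x), rate)))
  n_frames <- 151
  # bin quantization can tie adjacent frames' quartile frequencies, so the
  # argmax may land on either end of a tie run: allow two frames of slack
  expect_lte(abs(f_rev[["dfa1maloc"]] - (1 - f_fwd[["dfa1maloc"]])), 2 / (n_frames - 1))
  expect_lte(abs(f_rev[["dfa2maloc"]] - (1 - f_fwd[["dfa2maloc"]])), 2 / (n_frames - 1))
  stable <- c("duration", "dfa1mean", "dfa2mean", "df1max", "df1min", "df1mean",
              "diffreq", "fp1max", "fp1mean", "fp1amean", "ranmean",
              "pfmax", "pfmin", "pfmean", "noise", "tonality")
  expect_equal(f_rev[stable], f_fwd[stable], tolerance = 1e-8)
})

test_that("pure-tone frequency is recovered within one bin at all rates", {
  set.seed(13)
  for (i in 1:50) {
    rate <- sample(c(22050, 11025, 4000), 1)
    freq <- runif(1, 0.1, 0.4) * rate
    s <- spectrogram(tone_wave(freq, duration_s = 0.12, rate = rate))
    f <- extract_features(s)
    expect_lte(abs(f[["pfmean"]] - freq), s$bin_hz)
  }
})

test_that("degenerate segments are rejected or flagged", {
  expect_error(extract_features(spectrogram(call_wave(rep(0, 1000), 22050))),
               "all-silent")
})
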