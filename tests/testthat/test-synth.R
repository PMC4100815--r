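test_that("feature tables are reproducible bit-for-bit from the seed", {
  spec <- signature_spec(calls_per_caller = c(9, 7, 5), seed = 123)
  expect_identical(synth_feature_table(spec), synth_feature_table(spec))
  spec2 <- signature_spec(calls_per_caller = c(9, 7, 5), seed = 124)
  expect_false(identical(synth_feature_table(spec), synth_feature_table(spec2)))
})

test_that("generated tables carry the declared structure", {
  spec <- signature_spec(n_callers = 4, calls_per_caller = c(8, 6, 5, 5),
                         call_types = c("hum", "scream"),
                         segments_per_sequence = 2, seed = 14)
  tab <- synth_feature_table(spec)
  expect_equal(nrow(tab), 2 * (8 + 6 + 5 + 5))
  expect_setequal(unique(tab$call_type), c("hum", "scream"))
  expect_true(all(feature_names() %in% names(tab)))
  expect_silent(call_records(tab[setdiff(names(tab), feature_names())]))
  counts <- table(tab$sequence_id)
  expect_true(all(counts <= 2))
  expect_error(signature_spec(signature_parameters = "bogus"), "unknown")
  expect_error(signature_spec(call_types = "bark"), "unknown")
  expect_error(signature_spec(effect_size = -1), ">= 0")
})

test_that("a planted 3-SD signature supports near-perfect classification", {
  tab <- synth_feature_table(signature_spec(
    calls_per_caller = 20, effect_size = 3,
    signature_parameters = c("pfmean", "diffreq"), seed = 1))
  d <- suppressWarnings(stepwise_dfa(tab))
  expect_gte(d$leave_one_out$overall, 90)
})

test_that("leave-one-out accuracy is monotone in effect size", {
  pars <- c("pfmean", "diffreq")
  acc <- vapply(c(0, 1, 2, 3), function(es) {
    mean(vapply(1:20, function(s) {
      tab <- synth_feature_table(signature_spec(
        calls_per_caller = 15, effect_size = es,
        signature_parameters = pars, seed = 500 + s))
      suppressWarnings(loo_classification(tab, pars)$overall)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
})

test_that("harmonic waveforms surface the planted fundamental", {
  set.seed(40)
  w <- synth_waveform("harmonic_series", duration_s = 0.4, rate = 11025,
                      f0 = 300, snr_db = 40)
  s <- spectrogram(w)
  f <- extract_features(s)
  harmonic_offset <- abs(f[["pfmean"]] - 300 * round(f[["pfmean"]] / 300))
  expect_lte(harmonic_offset, s$bin_hz)
})

test_that("a clean unmodulated harmonic call is fully tonal", {
  set.seed(41)
  w <- synth_waveform("pulsed_grunt", duration_s = 0.3, rate = 4000,
                      f0 = 120, pulse_rate = 0, snr_db = Inf)
  f <- extract_features(spectrogram(w))
  expect_equal(unname(f["tonality"]), 100)
  expect_equal(unname(f["noise"]), 0)
})

test_that("waveform templates produce valid, distinct classes", {
  set.seed(42)
  for (tmpl in c("harmonic_series", "pulsed_grunt", "noisy_scream")) {
    w <- synth_waveform(tmpl, duration_s = 0.25, rate = 11025)
    expect_s3_class(w, "call_wave")
    expect_lte(max(abs(w$samples)), 1)
    expect_silent(extract_features(spectrogram(w)))
  }
  # a broadband scream at its native analysis rate reads as mostly noisy
  set.seed(43)
  f_noise <- extract_features(spectrogram(
    synth_waveform("noisy_scream", duration_s = 0.25, rate = 22050,
                   band = c(300, 10800), snr_db = 15)))
  expect_gte(f_noise[["noise"]], 50)
})

test_that("two callers split by f0 are separable through the audio pipeline", {
  ds <- synth_dataset(n_callers = 2, calls_per_caller = 20,
                      call_type = "hoot_series", effect_size = 3,
                      f0_base = 300, f0_within_sd = 10, seed = 2,
                      out_dir = withr::local_tempdir())
  feats <- features_from_audio(ds$records)
  res <- suppressWarnings(loo_classification(
    feats, c("pfmax", "pfmin", "pfmean", "dfa1mean", "dfa2mean")))
  # exceed the upper 95% binomial bound at chance 50%
  expect_gt(res$overall, 100 * qbinom(0.95, 40, 0.5) / 40)
})
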