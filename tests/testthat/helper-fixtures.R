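# Fixtures built in code: tones, frame spectra, toy record tables.

tone_wave <- function(freq, duration_s = 0.5, rate = 22050, amp = 0.8) {
  n <- round(duration_s * rate)
  call_wave(amp * sin(2 * pi * freq * (seq_len(n) - 1) / rate), rate)
}

# Magnitude spectrum of a single windowed frame (for frame-level oracles).
frame_spectrum <- function(x, fft_len = 1024L, window = signal::hamming(length(x))) {
  Mod(stats::fft(c(x * window, rep(0, fft_len - length(x)))))[seq_len(fft_len / 2 + 1)]
}

toy_records <- function(n = 6, caller = "F1", call_type = "threat_grunt",
                        t0 = 0, gap = 7200, quality = TRUE, seq_ids = NULL,
                        prefix = caller) {
  data.frame(
    segment_id = sprintf("%s_%s_%02d", prefix, call_type, seq_len(n)),
    caller_id = rep(caller, n),
    call_type = rep(call_type, n),
    sequence_id = seq_ids %||% sprintf("%s_%s_s%02d", prefix, call_type, seq_len(n)),
    timestamp = t0 + gap * (seq_len(n) - 1),
    audio_path = rep("", n),
    quality_ok = rep(quality, length.out = n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Feature-space table with one informative column among noise, for DFA tests.
planted_table <- function(n_per = 15, n_callers = 2, shift = 10,
                          informative = "duration", n_noise = 4, seed = 42) {
  set.seed(seed)
  pars <- setdiff(feature_names(), informative)[seq_len(n_noise)]
  callers <- sprintf("F%d", seq_len(n_callers))
  d <- data.frame(caller_id = rep(callers, each = n_per))
  d[[informative]] <- rnorm(n_per * n_callers) +
    shift * (as.integer(factor(d$caller_id)) - 1)
  for (p in pars) d[[p]] <- rnorm(n_per * n_callers)
  d
}

# Hand-rolled equal-prior linear discriminant classifier (pooled covariance),
# independent of MASS, used as the leave-one-out oracle.
hand_ldc_predict <- function(Xtr, gtr, xnew) {
  lev <- sort(unique(as.character(gtr)))
  mus <- lapply(lev, function(l) colMeans(Xtr[gtr == l, , drop = FALSE]))
  W <- Reduce(`+`, lapply(lev, function(l) {
    crossprod(scale(Xtr[gtr == l, , drop = FALSE], center = TRUE, scale = FALSE))
  }))
  S <- W / (nrow(Xtr) - length(lev))
  Sinv <- solve(S)
  scores <- vapply(mus, function(mu) {
    dx <- as.numeric(xnew) - mu
    -0.5 * as.numeric(t(dx) %*% Sinv %*% dx)
  }, numeric(1))
  lev[which.max(scores)]
}
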