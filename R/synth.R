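# Synthetic vocalization data with controllable individual signatures.

# Plausible repertoire-level baselines (global mean and within-caller SD)
# for the twenty parameters, loosely shaped after low-pitched great-ape
# calls analysed at a few kHz bandwidth.
param_baselines <- function() {
  data.frame(
    parameter = feature_names(),
    mean = c(400, 300, 0.5, 600, 0.5, 500, 200, 350, 250, 2.5, 1.5,
             400, 300, 0.6, 800, 700, 250, 450, 30, 40),
    within_sd = c(100, 80, 0.15, 150, 0.15, 120, 60, 90, 70, 0.6, 0.4,
                  100, 80, 0.15, 200, 180, 70, 110, 10, 12),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic dataset with planted caller signatures
#'
#' Defines the study conditions a synthetic feature table (or waveform set)
#' emulates: a handful of callers with unequal sample sizes (default
#' 62/58/29 calls, mirroring a typical unbalanced field design), caller
#' signatures planted on a subset of parameters as mean shifts measured in
#' units of the within-caller SD, and optional sequence structure for call
#' types built from repeated segments.
#'
#' @param n_callers Number of callers (2-6 is typical).
#' @param calls_per_caller Calls per caller for each call type; recycled to
#'   `n_callers`.
#' @param call_types Call types to simulate (subset of [call_types()]).
#' @param effect_size Caller mean shift on the signature parameters, in
#'   within-caller SD units. 0 makes callers exchangeable.
#' @param signature_parameters Parameters carrying true caller signal.
#' @param within_sd Optional named vector overriding the default
#'   within-caller SDs.
#' @param segments_per_sequence Call segments per sequence (> 1 adds a
#'   shared per-sequence random intercept, see `sequence_sd_frac`).
#' @param sequence_sd_frac With repeated segments, the fraction of the
#'   within-caller SD attributed to the per-sequence intercept (total
#'   within-caller variance is preserved).
#' @param seed Integer seed; identical specs reproduce identical data.
#' @return A list of class `signature_spec`.
#' @export
signature_spec <- function(n_callers = 3,
                           calls_per_caller = c(62, 58, 29),
                           call_types = "threat_grunt",
                           effect_size = 1.5,
                           signature_parameters = c("diffreq", "dfa1maloc", "pfmean"),
                           within_sd = NULL,
                           segments_per_sequence = 1,
                           sequence_sd_frac = 0.3,
                           seed = 1) {
  bad <- setdiff(signature_parameters, feature_names())
  if (length(bad)) {
    stop_validation("unknown signature parameter(s): ", paste(bad, collapse = ", "))
  }
  bad_ct <- setdiff(call_types, call_types())
  if (length(bad_ct)) {
    stop_validation("unknown call type(s): ", paste(bad_ct, collapse = ", "))
  }
  if (effect_size < 0) stop_validation("effect_size must be >= 0")
  calls_per_caller <- rep_len(calls_per_caller, n_callers)
  if (any(calls_per_caller < 1)) stop_validation("calls_per_caller must be >= 1")
  structure(list(
    n_callers = as.integer(n_callers),
    calls_per_caller = as.integer(calls_per_caller),
    call_types = call_types,
    effect_size = effect_size,
    signature_parameters = signature_parameters,
    within_sd = within_sd,
    segments_per_sequence = as.integer(segments_per_sequence),
    sequence_sd_frac = sequence_sd_frac,
    seed = as.integer(seed)
  ), class = "signature_spec")
}

# Caller offsets on the signature parameters, standardized across callers
# (mean 0, SD 1) so that effect_size is exactly the between-caller SD in
# within-caller SD units.
caller_offsets <- function(n_callers, parameters) {
  z <- matrix(stats::rnorm(n_callers * length(parameters)),
              nrow = n_callers,
              dimnames = list(NULL, parameters))
  if (n_callers > 1L) {
    z <- apply(z, 2, function(v) (v - mean(v)) / stats::sd(v))
  }
  z
}

#' Generate a synthetic feature table
#'
#' Draws calls directly in feature space: per caller, the mean of each
#' signature parameter is shifted by
#' `effect_size * within_sd * caller offset` (offsets drawn once per caller
#' from the seed and standardized across callers); calls are multivariate
#' normal around the caller means with diagonal within-caller covariance.
#' With repeated segments, part of the within-caller variance is moved into
#' a shared per-sequence intercept. Identical specs (including the seed)
#' reproduce identical tables.
#'
#' @param spec A [signature_spec()].
#' @return Feature table: `segment_id`, `caller_id`, `call_type`,
#'   `sequence_id`, `timestamp`, `quality_ok`, then the twenty parameters.
#' @export
synth_feature_table <- function(spec) {
  stopifnot(inherits(spec, "signature_spec"))
  base <- param_baselines()
  wsd <- stats::setNames(base$within_sd, base$parameter)
  if (!is.null(spec$within_sd)) wsd[names(spec$within_sd)] <- spec$within_sd
  mu0 <- stats::setNames(base$mean, base$parameter)
  pars <- feature_names()

  with_seed(spec$seed, {
    rows <- list()
    for (ct in spec$call_types) {
      z <- caller_offsets(spec$n_callers, spec$signature_parameters)
      for (ci in seq_len(spec$n_callers)) {
        caller <- sprintf("F%d", ci)
        mu <- mu0
        mu[spec$signature_parameters] <- mu[spec$signature_parameters] +
          spec$effect_size * wsd[spec$signature_parameters] * z[ci, ]
        n <- spec$calls_per_caller[ci]
        spq <- spec$segments_per_sequence
        n_seq <- ceiling(n / spq)
        seq_of_call <- rep(seq_len(n_seq), each = spq)[seq_len(n)]
        frac <- if (spq > 1L) spec$sequence_sd_frac else 0
        seq_fx <- matrix(stats::rnorm(n_seq * length(pars)), nrow = n_seq) *
          rep(frac * wsd[pars], each = n_seq)
        call_sd <- sqrt(pmax(0, 1 - frac^2)) * wsd[pars]
        vals <- matrix(stats::rnorm(n * length(pars)), nrow = n) *
          rep(call_sd, each = n) +
          rep(mu[pars], each = n) +
          seq_fx[seq_of_call, , drop = FALSE]
        colnames(vals) <- pars
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(
            segment_id = sprintf("%s_%s_c%03d", ct, caller, seq_len(n)),
            caller_id = caller,
            call_type = ct,
            sequence_id = sprintf("%s_%s_s%03d", ct, caller, seq_of_call),
            timestamp = 7200 * (seq_of_call - 1) + 2 * (seq_len(n) - 1),
            quality_ok = TRUE,
            stringsAsFactors = FALSE
          ),
          as.data.frame(vals)
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Synthesize one call-segment waveform
#'
#' Three templates mimic the gross structure of the repertoire's call
#' classes: `"harmonic_series"` (f0 plus harmonics with a spectral tilt —
#' hoots and hums), `"pulsed_grunt"` (amplitude-modulated low-frequency
#' harmonic stack — grunts and grumbles), and `"noisy_scream"` (band-passed
#' noise with caller-shiftable band edges). A Gaussian noise floor is added
#' at `snr_db` (use `Inf` for none); onset/offset are ramped over 10 ms and
#' the peak is normalized to 0.9.
#'
#' @param template One of `"harmonic_series"`, `"pulsed_grunt"`,
#'   `"noisy_scream"`.
#' @param duration_s Segment duration in seconds.
#' @param rate Sampling rate in Hz.
#' @param f0 Fundamental (harmonic templates) in Hz.
#' @param tilt Harmonic amplitude decay exponent (amplitude of harmonic h is
#'   `h^-tilt`).
#' @param n_harmonics Number of harmonics (capped below Nyquist).
#' @param band Length-2 passband in Hz (noisy template).
#' @param pulse_rate Amplitude-modulation rate in Hz (pulsed template); 0
#'   disables modulation.
#' @param snr_db Signal-to-noise ratio of the additive noise floor in dB.
#' @return A [call_wave()].
#' @export
synth_waveform <- function(template = c("harmonic_series", "pulsed_grunt",
                                        "noisy_scream"),
                           duration_s = 0.5, rate = 11025, f0 = 300,
                           tilt = 1, n_harmonics = 6, band = c(300, 10800),
                           pulse_rate = 20, snr_db = 30) {
  template <- match.arg(template)
  n <- max(256L, round(duration_s * rate))
  t <- (seq_len(n) - 1) / rate

  if (template == "harmonic_series" || template == "pulsed_grunt") {
    h_max <- max(1L, min(n_harmonics, floor(0.45 * rate / f0)))
    x <- rowSums(vapply(seq_len(h_max), function(h) {
      (h^-tilt) * sin(2 * pi * h * f0 * t + stats::runif(1, 0, 2 * pi))
    }, numeric(n)))
    if (template == "pulsed_grunt" && pulse_rate > 0) {
      x <- x * (0.5 + 0.5 * cos(2 * pi * pulse_rate * t))
    }
  } else {
    lo <- max(band[1], 0)
    hi <- min(band[2], rate / 2)
    spec <- stats::fft(stats::rnorm(n))
    freq <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) * rate / n
    spec[abs(freq) < lo | abs(freq) > hi] <- 0
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
  }

  ramp_n <- min(round(0.01 * rate), n %/% 4)
  if (ramp_n > 0) {
    env <- rep(1, n)
    env[seq_len(ramp_n)] <- seq(0, 1, length.out = ramp_n)
    env[n - ramp_n + seq_len(ramp_n)] <- seq(1, 0, length.out = ramp_n)
    x <- x * env
  }
  if (is.finite(snr_db)) {
    noise_sd <- stats::sd(x) * 10^(-snr_db / 20)
    x <- x + stats::rnorm(n, sd = noise_sd)
  }
  call_wave(0.9 * x / max(abs(x)), rate)
}

template_for_type <- function(call_type) {
  switch(call_type,
         hum = , hoot_series = "harmonic_series",
         scream = "noisy_scream",
         "pulsed_grunt")
}

#' Generate a synthetic audio dataset with caller f0 signatures
#'
#' Builds call records plus waveforms for one call type: each caller gets an
#' f0 offset of `effect_size * f0_within_sd` times a standardized unit
#' offset, and each call jitters around the caller f0 with SD
#' `f0_within_sd`. Sequences are spaced two hours apart so the
#' independence filter keeps them all. The noisy template shifts its lower
#' band edge instead of f0.
#'
#' @param n_callers,calls_per_caller,effect_size,seed As in [signature_spec()].
#' @param call_type One call type; picks the waveform template and the
#'   analysis rate.
#' @param f0_base Repertoire-level fundamental in Hz.
#' @param f0_within_sd Within-caller f0 SD in Hz.
#' @param duration_s Segment duration in seconds.
#' @param snr_db Noise floor SNR.
#' @param rate Recording rate (defaults to the call type's analysis rate).
#' @param out_dir Directory to write WAV files into; `NULL` keeps waveforms
#'   in memory.
#' @return List with `records` (call-record table; `audio_path` filled when
#'   `out_dir` is given) and `waves` (list of [call_wave()], `NULL`ed when
#'   written to disk).
#' @export
synth_dataset <- function(n_callers = 3, calls_per_caller = 20,
                          call_type = "hoot_series", effect_size = 2,
                          f0_base = 300, f0_within_sd = 10,
                          duration_s = 0.4, snr_db = 30,
                          rate = select_band_rate(call_type),
                          out_dir = NULL, seed = 1) {
  calls_per_caller <- rep_len(calls_per_caller, n_callers)
  template <- template_for_type(call_type)
  with_seed(seed, {
    z <- caller_offsets(n_callers, "f0")[, 1]
    recs <- list()
    waves <- list()
    for (ci in seq_len(n_callers)) {
      caller <- sprintf("F%d", ci)
      f0_caller <- f0_base + effect_size * f0_within_sd * z[ci]
      for (j in seq_len(calls_per_caller[ci])) {
        f0 <- f0_caller + stats::rnorm(1, sd = f0_within_sd)
        w <- if (template == "noisy_scream") {
          synth_waveform("noisy_scream", duration_s = duration_s, rate = rate,
                         band = c(800 + 4 * (f0 - f0_base), 10500),
                         snr_db = snr_db)
        } else {
          synth_waveform(template, duration_s = duration_s, rate = rate,
                         f0 = f0, snr_db = snr_db)
        }
        id <- sprintf("%s_%s_c%03d", call_type, caller, j)
        waves[[id]] <- w
        recs[[length(recs) + 1L]] <- data.frame(
          segment_id = id, caller_id = caller, call_type = call_type,
          sequence_id = sprintf("%s_%s_s%03d", call_type, caller, j),
          timestamp = 7200 * (j - 1),
          audio_path = paste0(id, ".wav"), quality_ok = TRUE,
          stringsAsFactors = FALSE
        )
      }
    }
    records <- do.call(rbind, recs)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (id in names(waves)) {
        write_wav(waves[[id]], file.path(out_dir, paste0(id, ".wav")))
      }
      records$audio_path <- file.path(out_dir, records$audio_path)
      waves <- NULL
    }
    list(records = records, waves = waves)
  })
}
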