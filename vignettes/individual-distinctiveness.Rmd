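---
title: "Quantifying individual distinctiveness across a vocal repertoire"
author: "vocalid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying individual distinctiveness across a vocal repertoire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalid)
```

## The scientific question

Many animals produce a repertoire of discrete call types, and listeners can
often tell callers apart by voice alone. Two classic hypotheses make
opposite predictions about *which* calls should be most individually
distinct: calls exchanged over long distances (no visual cues, so identity
must travel in the sound) versus calls used in close-range social
interaction (where knowing who is talking matters most). Testing either
requires measuring, for every call type, (a) how variable the calls are
within and between individuals and (b) how reliably calls can be assigned
to their caller.

`vocalid` implements that measurement pipeline for call-segment audio of
wild western gorilla females (eight call types: single grunt, double grunt,
grumble, threat grunt, copulation grunt, hum, hoot series, scream), but
nothing in the machinery is species specific.

## Analysis unit and inclusion rules

The unit of analysis is the **call segment** — the repeated sub-unit of a
vocalization — not the whole call. Three rules decide what enters the
analysis (`filter_call_records()`):

1. segments failing the recording-quality flag are dropped;
2. for call types built from repeated segments (threat grunt, copulation
   grunt, hoot series), only *independent* sequences are used: a sequence
   counts only if it starts at least one hour (`min_gap_s = 3600`) after
   the previously retained sequence of the same caller and call type;
3. a caller contributes to a call type only with at least four surviving
   calls (`min_calls = 4`).

The gap rule is applied per (caller, call type). Its greedy earliest-first
form makes the filter idempotent.

## Spectrograms

Segments are downsampled to one of three analysis rates chosen by the call
type's frequency range (22050, 11025 or 4000 Hz; `select_band_rate()`).
Which call type maps to which rate is a configurable package default
chosen by the calls' typical frequency content (broadband screams at
22050 Hz, harmonically rich threat grunts and hoots at 11025 Hz, low
grunts and hums at 4000 Hz), since only the three rates themselves are
fixed by the protocol.

Spectrograms use 256-sample frames zero-padded to a 1024-point FFT with
93 % overlap. We read "1024-pt FFT length containing 256 samples" as a
256-sample analysis frame zero-padded fourfold, so the hop is
`round(256 * 0.07) = 18` samples, the frame count is
`floor((N - 256)/18) + 1` and the bin spacing `rate/1024`. The window
defaults to Hamming and is configurable; window choice affects the
tonality and noisiness estimates most, which is why it is surfaced as an
argument rather than buried.

## The twenty acoustic parameters

`extract_features()` computes, per segment: duration; means and
peak-location of the frequencies at which 25 % / 50 % of frame energy is
reached (`dfa1*`, `dfa2*`); statistics of the first (lowest) dominant
frequency band, the mean band count, the minimum spacing and amplitude
ratio of the first two bands (`df1*`, `diffreq`, `diffmean`, `ampratio1`);
the first spectral peak (`fp1*`); the mean above-threshold frequency range
(`ranmean`); peak-frequency statistics (`pf*`); and the percentages of
noisy and tonal frames. Frequency-modulation and start/end-frequency
measures are deliberately out of scope.

Numerical choices that the original measurement software does not expose
had to be fixed here; all are configurable and documented as surrogates,
not as reconstructions of that software's internals:

* **Dominant-band threshold** (`band_threshold_db`, default −24 dB relative
  to the frame peak). This is the single most consequential free parameter:
  it defines what counts as a band, hence `df1*`, `diffreq`, `diffmean`,
  `ampratio1`, `fp1*` and `ranmean`.
* **Tonality** is judged by spectral flatness (Wiener entropy) of the
  frame's power spectrum, block-averaged over 16 bins to tame periodogram
  variance (raw periodogram flatness of white noise centres near 0.56, not
  1; after 16-bin averaging it centres near 0.83). A frame is tonal below
  0.3, noisy above 0.7, and *neither* in between — noise % and tonality %
  therefore need not sum to 100. Because flatness is computed across the
  full analysis band, band-limited noise can legitimately read as
  "neither"; the synthetic scream template is broadband for this reason.
* **Location parameters** (`dfa1maloc`, `dfa2maloc`) are the relative
  temporal position in [0, 1] of the frame attaining the maximum quartile
  frequency (0.5 for a single-frame segment; ties resolve to the earliest
  frame).
* Zero-energy frames are excluded from every aggregation; all thresholds
  are relative, so every parameter is invariant to amplitude scaling.
* When no frame shows two dominant bands, `diffmean` and `ampratio1` are
  missing; rows with missing values are deleted listwise before
  discriminant analysis (parameters missing for an entire call type are
  dropped instead, with a warning).

## Variability and the potential for identity coding

For each parameter and call type (`variability_summary()`):

* `CV_inter = 100 · SD/mean` over the pooled calls of the type;
* `CV_intra` = unweighted mean of per-caller CVs (the sample SD, n − 1, is
  used throughout — the protocol does not state a denominator);
* `PIC = CV_inter / CV_intra`, with PIC > 1 read as between-caller
  variation exceeding within-caller variation. PIC is reported, never
  silently thresholded.

Averaging the per-parameter CVs gives `CV_inter_mean`, `CV_intra_mean` and
the call type's overall PIC. An alternative composite "SD_intra" phrase in
the source protocol is internally inconsistent with the CV_intra formula
it accompanies; only the CV formula is implemented. CVs are compared
across call types with the Friedman test (`friedman_test()`, mid-ranks,
chi-squared approximation — matching standard statistical software rather
than exact enumeration at 20 blocks).

Note that CV and PIC presume ratio-scale, positive-mean parameters;
location parameters near 0 can produce unstable CVs, which is a property
of the statistic, not of the implementation.

## Discriminant analysis and its permutation test

Per call type, `stepwise_dfa()` performs forward-stepwise selection
minimizing Wilks' Λ with partial-F entry/removal thresholds (defaults
3.84/2.71, the SPSS defaults — the protocol names only "stepwise").
Canonical functions come from the eigen-decomposition of
\(W^{-1}B\); Λ of the selected model satisfies
\(\Lambda = \prod_i 1/(1+\lambda_i)\), tested by
\(\chi^2 = -(n - 1 - (p+g)/2)\ln\Lambda\) with \(p(g-1)\) df. Loadings are
pooled within-group correlations between parameters and discriminant
scores; parameters loading above 0.45 in absolute value go on to the
mixed-model confirmation.

Classification uses equal priors, so chance is \(100/g\) % (33.3 % for
three callers, 50 % for two). Resubstitution and leave-one-out (U-method)
rates are both reported; their agreement indicates profile stability.
Leave-one-out refits on all remaining calls with the parameter set fixed
beforehand, and skips folds that would leave a caller with fewer than two
calls. Ties resolve to the lexicographically smallest caller, keeping runs
deterministic.

`pdfa()` attaches permutation p-values to both rates: `P1` for the fitting
DFA, `P2` for the cross-validated one, each as
\((b + 1)/(m + 1)\) where `b` counts null rates at or above the observed —
the estimator cannot return zero. Unbalanced designs are handled by
averaging the observed rates over 100 random balanced subsets (minimum
per-caller n from every caller) and drawing a fresh balanced subset in
each of the 1000 null iterations. When repeated-segment sequences exist,
labels are permuted at the sequence level so that non-independent segments
travel together; whether the original analysis restricted its permutations
this way is not stated, so this choice is ours and is configurable by
removing the sequence column.

`lmm_parameter_significance()` fits, per tested parameter, caller identity
as a fixed effect with a sequence random intercept, and compares against
the no-caller model by likelihood ratio (ML fits), falling back to a
fixed-effects ANOVA when no sequence structure exists or the mixed model
fails. P-values are Hochberg-corrected (`hochberg_adjust()`, step-up).
Finally `compare_call_types()` asks whether call types differ in
individual distinctiveness: per-caller leave-one-out proportions are
arcsine-square-root transformed and modelled with call type fixed and
caller identity and the per-cell call count as random intercepts
(Satterthwaite F). The exact random structure of the original analysis is
under-specified; ours is documented, not asserted as theirs.

## The synthetic-data generator

Because no recordings are deposited with the original study, every stage
is validated on synthetic data with known ground truth.

`synth_feature_table()` draws calls directly in feature space: caller
means are the repertoire baselines shifted by
`effect_size × within_sd × offset` on the chosen signature parameters,
with offsets drawn once per caller and standardized across callers so
`effect_size` is exactly the between-caller SD in within-caller SD units.
Within-caller covariance is diagonal (the study provides no covariance
information); repeated-segment types move 30 % of the within-caller SD
into a shared per-sequence intercept, preserving total variance. Defaults
mirror the study's shape: 3 callers, unbalanced 62/58/29 calls, signature
on `diffreq`, `dfa1maloc` and `pfmean` (the parameters most often found
discriminating), and `effect_size = 1.5`, which lands classification and
overall-PIC values in the ranges the field study reported (~75–95 %
correct, overall PIC a little above 1). `effect_size = 0` makes callers
exchangeable — the null used for calibration.

`synth_waveform()` provides three waveform templates (harmonic series,
pulsed grunt, broadband noisy scream) and `synth_dataset()` plants caller
signatures in the fundamental (or band edge), writes WAVs and metadata,
and so exercises the audio path end to end.

What the generator does *not* emulate: microphone and habitat noise
spectra, reverberation, amplitude cues, graded intermediates between call
types, or realistic parameter correlations. Passing tests therefore show
that the statistics recover signatures of the planted kind at the planted
strength — not that every real-world recording condition is handled.

## Problem sizes and determinism

All randomness flows from explicit integer seeds (`signature_spec(seed=)`,
`pdfa(seed=)`, `run_config(seed=)`); identical configurations reproduce
outputs bit for bit. The test suite uses reduced but statistically
meaningful sizes chosen as a deliberate design point: pDFA calibration
uses 100 null tables of 3 × 20 calls at 200 permutations; signature
detection uses 20 replicates; the audio round trip uses 3 callers × 20
hoots of 0.3 s. The shipped analysis defaults remain the full 100
selections × 1000 permutations.

## Known limitations

* The exact definitions of the band threshold, tonality criterion and
  location units in the original measurement software are not recoverable;
  ours are documented surrogates, and absolute feature values should not
  be compared across implementations.
* CV/PIC are undefined for zero-mean parameters and unstable near zero.
* Leave-one-out accuracies within one table are correlated; their spread
  under the null is far wider than a binomial interval, which matters when
  interpreting single-table accuracies near chance.
* The chi-squared approximations (Wilks test, Friedman) are asymptotic;
  for the smallest call-type samples the pDFA permutation p-values are the
  ones to trust.
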