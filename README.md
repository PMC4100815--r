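# vocalid

Individual distinctiveness across an animal vocal repertoire.

`vocalid` is for bioacousticians asking, for *every* call type a species
produces, whether calls carry caller identity — and whether some call types
carry more of it than others. It implements the full analysis chain used in
field studies of wild western gorilla females (eight call types, two to
six callers, unbalanced samples), from call-segment audio to the
statistics a results table reports:

* **Feature extraction** — spectrograms of call segments (256-sample
  frames zero-padded to a 1024-pt FFT, 93 % overlap, per-call-type
  analysis rates of 22050/11025/4000 Hz) and twenty acoustic parameters
  per segment: duration, energy-quartile frequencies and their temporal
  locations (dfa1/dfa2), dominant-frequency-band structure (df1*,
  diffreq, diffmean, ampratio1), first spectral peak (fp1*), frequency
  range, peak frequency (pf*), and the percentages of noisy and tonal
  frames.
* **Acoustic variability** — per-parameter coefficients of variation,
  pooled across callers (CV<sub>inter</sub> = 100·SD/mean) and averaged
  within callers (CV<sub>intra</sub>), and the **potential for identity
  coding**, PIC = CV<sub>inter</sub>/CV<sub>intra</sub>; PIC > 1 means
  between-caller variation exceeds within-caller variation. Friedman rank
  tests compare CVs and PIC across call types.
* **Individual distinctiveness** — stepwise discriminant function
  analysis (Wilks' Λ minimization, F-to-enter 3.84 / F-to-remove 2.71),
  leave-one-out (U-method) cross-validated classification with equal
  priors (chance = 100/g %), **permuted DFA** p-values P₁ (fitting) and
  P₂ (cross-validated) with 100 balanced selections × 1000 permutations
  for unbalanced designs, linear-mixed-model confirmation of parameters
  loading > 0.45 with Hochberg correction, and an arcsine-LMM comparison
  of distinctiveness across call types.
* **Synthetic data** — a generator that plants caller signatures of known
  strength in feature tables or in actual waveforms (harmonic, pulsed and
  noisy templates), so every stage is testable without field recordings.

## Worked example

Simulate two call types under study-like conditions — three callers with
62/58/29 calls each and a 1.5-within-SD caller signature on `diffreq`,
`dfa1maloc` and `pfmean` — then run the whole pipeline:

```r
library(vocalid)

tab <- synth_feature_table(signature_spec(
  call_types = c("threat_grunt", "hoot_series"),
  segments_per_sequence = 3, seed = 42))

cfg <- run_config(n_selections = 100, n_permutations = 1000, seed = 42)
run <- run_pipeline(cfg, features = tab)
run
#> Individual-distinctiveness run
#>     call_type   n dfa_pct       P1 cdfa_pct       P2 chance wilks_lambda
#>  threat_grunt 149    93.3 0.000999     91.9 0.000999   33.3        0.106
#>   hoot_series 149    91.3 0.000999     90.6 0.000999   33.3        0.129
#>    significant_parameters
#>  diffreq dfa1maloc pfmean
#>  diffreq pfmean dfa1maloc
#> Across call types: F(1, 2.0) = 0.002, p = 0.970
```

Reading the table: of 149 threat grunts, 93.3 % are assigned to the right
caller by the fitted DFA and 91.9 % under leave-one-out, against a 33.3 %
chance level for three callers; both rates beat all 1000 label
permutations (P = 1/1001 ≈ 0.001, the estimator's floor). The stepwise
search recovered exactly the three planted signature parameters, and they
remain significant in the mixed models after Hochberg correction. The
across-type comparison finds no difference in distinctiveness between the
two call types (p = 0.97) — as it should, since both carry the same
planted effect.

Variability statistics for one call type:

```r
s <- variability_summary(tab, "threat_grunt")
s$overall
#>      call_type cv_inter_mean cv_intra_mean overall_pic n_calls n_callers
#> 1 threat_grunt      28.89454      27.12728    1.065147     149         3

head(s$per_parameter[c("parameter", "cv_inter", "cv_intra", "pic")], 4)
#>   parameter cv_inter cv_intra       pic
#> 1  duration 24.31089 24.09166 1.0090996
#> 2  dfa1mean 27.01466 26.42279 1.0223997
#> 3 dfa1maloc 42.30916 33.23773 1.2729256
#> 4  dfa2mean 26.28488 26.95390 0.9751791
```

The signature parameter `dfa1maloc` shows PIC ≈ 1.27; pure-noise
parameters sit near 1. The overall PIC of 1.07 is what a modest
(1.5-within-SD, three-parameter) signature diluted over twenty parameters
looks like.

The audio route is identical but starts from WAV files and a metadata
table (`run_config(meta_csv = ..., audio_dir = ...)`), or in one call:
`features_from_audio()`. `synth_dataset()` writes a ready-made synthetic
WAV corpus for trying it.

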