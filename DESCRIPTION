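Package: vocalid
Title: Individual Distinctiveness Across an Animal Vocal Repertoire
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies acoustic variability and individual distinctiveness
    across the call types of an animal vocal repertoire, with defaults drawn
    from field studies of wild western gorilla females. Provides spectrogram
    computation for call segments, extraction of twenty acoustic parameters
    (energy-quartile frequencies, dominant frequency bands, peak frequency,
    first spectral peak, tonality and noisiness), coefficients of variation
    and the potential-for-identity-coding (PIC) statistic, stepwise
    discriminant function analysis with leave-one-out cross-validation,
    permutation tests for classification rates (pDFA), mixed-model tests of
    discriminating parameters with Hochberg correction, and a synthetic-call
    generator (feature tables and waveforms) with controllable individual
    signatures for validating every pipeline stage.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    lme4,
    lmerTest,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
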