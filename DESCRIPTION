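Package: prestim
Title: Single-Trial Decoding of Pain Reports from Pre-Stimulus EEG Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study whether the brain state immediately before a
    near-threshold painful stimulus predicts the subjective report.  Provides
    a synthetic EEG cohort generator with a planted pre-stimulus high-gamma
    pain/no-pain effect, epoching and automatic artifact screening,
    rating-based condition balancing, DPSS multitaper spectral estimation,
    per-subject cross-validated linear support-vector-machine decoding with
    exact binomial significance, and group-level inference (within-subject
    label-permutation null, frequency-band attribution of classifier weights,
    stimulation-site lateralization ANOVA, pre/post-stimulus power and
    accuracy correlations, and trial-series autocorrelation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    generics,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
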