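Package: eegdfc
Title: Deep Feature Clustering for EEG Emotion Recognition
Version: 0.1.0
Authors@R:
    person("eegdfc", "developers", email = "eegdfc@example.org", role = c("aut", "cre"))
Description: A feature-selection pipeline for EEG-based emotion recognition.
    Multichannel EEG trials are decomposed by a fast empirical mode
    decomposition variant (halved extrema, normalized squared-difference
    sifting stop rule), rendered as analytic-wavelet time-frequency
    spectrogram images, and summarized into 1000-attribute deep-feature rows
    by pluggable extractors. Channels are scored by a discernibility
    (rough-set) entropy and selected by threshold or rank; per-model feature
    tables are fused into a combined feature vector, near-duplicate rows are
    eliminated, and Deep Feature Clustering (per-class k-means vocabularies
    plus histogram-of-features) reduces the representation before
    cross-validated SVM, k-NN and random-forest classification. A seeded
    synthetic-EEG generator with class-dependent band power makes the whole
    pipeline testable without licensed EEG corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    png,
    viridisLite,
    FNN,
    quadprog,
    digest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
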