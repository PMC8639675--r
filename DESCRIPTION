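Package: oscarith
Title: Oscillatory EEG Correlates of Arithmetic Strategy Use
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end pipeline for quantifying event-related
    desynchronization and synchronization (ERD/ERS) in theta and alpha
    frequency bands while children solve arithmetic problems with fact
    retrieval or procedural strategies. Covers the full analysis chain:
    stimulus-set validation, a synthetic multi-participant EEG and behavior
    generator, continuous-EEG cleaning (bad channels, common average
    reference, artifact masking, ICA-based ocular removal), band-power
    ERD/ERS computation with median horizontal and vertical averaging and
    region-of-interest aggregation, strategy-report consistency filtering
    with Cohen's kappa, and mixed-effects inference with Tukey-adjusted
    post-hoc contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
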