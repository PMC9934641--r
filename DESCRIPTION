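Package: wmdecode
Title: Time-Resolved Multivariate Decoding of Working-Memory Content from EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for decoding the category of maintained working-memory
    content (visual, spatial or verbal) from multichannel EEG with
    time-resolved multivariate pattern analysis. Provides a synthetic
    session generator (jittered delayed-recognition trial schedules,
    planted category-specific spatial patterns with 1/f background noise,
    injectable artifacts and per-trial behavioural responses), a
    preprocessing chain (zero-phase bandpass filtering, epoching,
    amplitude-threshold artifact rejection, behavioural scoring and
    subject exclusion rules), class-balanced pseudo-trial averaging, a
    shrinkage-regularised linear discriminant classifier, window-averaged
    and temporal-generalization decoding with repeated stratified
    cross-validation, and group-level inference (one-sided t-tests against
    chance, subject-wise permutation tests, paired Sensory-vs-Delay
    comparisons, accuracy correlations and age regressions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
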