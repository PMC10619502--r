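Package: lcsleep
Title: Locus Coeruleus MRI Contrast, Sleep EEG Energy Metrics, and
    Moderated Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools linking locus coeruleus (LC) neuroimaging measures to
    sleep. Computes the LC contrast ratio from neuromelanin-sensitive
    (magnetization-transfer) volumes via mask skeletonization and
    slice-wise normalization to a pontine reference region; derives sleep
    architecture metrics and cumulative overnight spectral energies (slow
    wave energy during SWS, theta energy during REM sleep) from a
    hypnogram, artifact annotations and a frontal EEG channel using
    Welch's overlapped-segment power spectral density estimator; and fits
    the downstream inference chain: moderated regression with per-group
    simple slopes and partial R-squared, Benjamini-Hochberg FDR,
    counterfactual mediation with bootstrap intervals, and an analytic
    sensitivity (minimum detectable effect size) analysis. A synthetic
    data module generates phantoms, hypnograms, staged EEG and cohort
    tables with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
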