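Package: docentropy
Title: Nonlinear EEG Entropy Analysis for Outcome Prediction in Disorders of
    Consciousness
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Approximate entropy (ApEn) and cross-approximate entropy (C-ApEn)
    analysis of 16-channel EEG for patients with unresponsive wakefulness
    syndrome (UWS) and minimally conscious state (MCS). Provides a synthetic
    cohort generator with controlled signal irregularity and channel coupling,
    EEG input/output (EDF and CSV) with 50 Hz notch filtering, artifact-free
    epoch selection and affected/unaffected montage remapping, fast
    box-assisted ApEn and C-ApEn with naive reference implementations,
    group-comparison statistics (Welch t tests and two-sample Hotelling T2
    over channel blocks), and a linear-probability prognostic regression of
    12-month modified Glasgow Outcome Scale improvement on demographics,
    CRS-R and entropy responses.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
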