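Package: mitransfer
Title: Cross-Subject Motor Imagery EEG Classification with Joint
    Spatial-Spectral Features and Instance Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-class motor imagery electroencephalography (EEG)
    classification across subjects. Epochs are band-pass filtered and windowed,
    spatial features are extracted with common spatial patterns (CSP), spectral
    features with Welch's averaged periodogram, and the concatenated joint
    feature vectors are classified by a TrAdaBoost instance-transfer ensemble
    whose initial sample weights come from kernel mean matching (KMM), so that
    source-subject trials are re-weighted toward the target subject's feature
    distribution. Includes a synthetic multi-subject EEG generator with
    controllable event-related desynchronization and inter-subject covariate
    shift, and leave-one-subject-out evaluation with the standard ablation
    configurations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    kernlab,
    rpart,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
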