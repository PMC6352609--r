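Package: kmibci
Title: Simulation and Analysis of Kinesthetic Motor-Imagery BCI Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether motor-imagery questionnaires predict
    brain-computer interface (BCI) performance. Provides a synthetic EEG
    cohort generator with controlled event-related desynchronization (ERD)
    and post-imagery beta rebound, EDF/TSV/CSV input-output, Butterworth
    band-pass filtering and protocol-aware epoching, four motor-imagery
    versus rest classifiers (CSP+LDA, MDRM, gfMDRM, TS+LR) built on the
    Riemannian geometry of symmetric positive-definite covariance matrices
    with stratified k-fold cross-validation, MIQ-RS questionnaire scoring
    with subgrouping and a correlation/effect-size battery under
    Benjamini-Hochberg control, and event-related spectral perturbation
    (ERSP) maps with permutation-FDR group comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
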