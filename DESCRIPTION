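Package: neopcg
Title: Neonatal Phonocardiogram Murmur Screening with Boosted Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening neonatal heart-sound (phonocardiogram)
    recordings for signatures of patent ductus arteriosus (PDA) and other
    congenital heart defects (CHD). Provides audio and segmentation I/O, a
    synthetic neonatal heart-sound simulator with ground-truth cycle
    segmentation, a 200-feature per-cycle extractor (sub-band energies,
    spectral and envelope descriptors, interval timing statistics),
    feature-level and decision-level aggregation across auscultation points,
    a verifiable reference implementation of regularized gradient-boosted
    trees alongside an xgboost-backed production path, gain-based feature
    importance with Top-N selection, and patient-independent nested
    cross-validation with explicit data-leakage settings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
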