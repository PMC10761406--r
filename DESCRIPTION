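Package: fluorscreen
Title: PFAS Feature Prioritization for Non-Target HRMS Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate per- and polyfluoroalkyl substance (PFAS)
    features in centroided LC/GC-HRMS runs. Provides a transparent feature
    finder for mzML data (or ingestion of external feature tables), carbon
    number estimation from the M+1 isotopologue, mass-defect filtering in the
    carbon-normalized MD/C vs m/C plane, Kendrick mass-defect detection of
    homologous series (e.g. CF2-spaced), MS2 diagnostic-fragment and
    fragment-mass-difference matching with formula propagation, adduct-aware
    suspect screening, extracted-ion-chromatogram utilities and coelution
    correlation for grouping in-source fragments and adducts, plus a fully
    ground-truthed synthetic data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mzR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
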