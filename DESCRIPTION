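Package: lumenprof
Title: Vascular Lumen Profiling from Micro-CT and Histology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies murine carotid-artery lumen remodeling from
    contrast-enhanced 3D micro-CT volumes and from histological sections.
    Implements midpoint-threshold lumen segmentation calibrated from blood
    and muscle regions of interest, maximal-inscribed-sphere centerline
    tracing ("virtual elastic sphere"), standardized nine-segment lumen
    profiles with circular cross-section areas, perimeter-based histology
    morphometry with a plaque-subtraction rule, and cross-modality agreement
    statistics (linear regression and Bland-Altman limits of agreement).
    A synthetic phantom generator produces curved, stenosed vessels with
    known ground truth plus virtual histology sections with shrinkage and
    compression artefacts, so the whole pipeline is testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    RNifti,
    tiff,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
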