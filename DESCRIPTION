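Package: vesiflux
Title: Quantitative Analysis of Vesicle Exocytosis, ER Calcium and FRAP Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative live-cell fluorescence imaging of
    neuronal secretion and endoplasmic-reticulum physiology: detection of
    single dense-core-vesicle fusion events from pHluorin time-lapse movies
    with NH4Cl-based total-pool normalization, SypHy synaptic-vesicle
    analysis (active-synapse classification, fused fraction, endocytosis
    kinetics), Hill-type calibration of ER-lumen GCaMP calcium indicators,
    caffeine store-depletion and refill metrics, FRAP recovery analysis,
    nested-culture ANOVA model comparison and a proteomics significance
    filter. A synthetic-data generator produces movies and traces with
    exact ground truth so the full pipeline is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    emmeans,
    EBImage,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
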