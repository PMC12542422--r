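Package: rbscreen
Title: High-Content Screening Analysis for Subcellular Translocation Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for image-based chemical screens
    that read out subcellular translocation phenotypes, such as nucleolar
    retention of ribosome biogenesis factors. Provides a synthetic-data
    generator for 384-well screens (plate layouts, per-cell ground truth,
    rendered two-channel fluorescence images), retrospective illumination
    correction with focus-based image exclusion, Hoechst-based nucleus
    segmentation with a cytoplasm-ring proxy, per-cell feature extraction,
    supervised eight-class phenotype classification, readout-specific hit
    rates, z'-factor plate quality control, hit calling against a
    DMSO-derived five-standard-deviation threshold, and quantification of
    gamma-H2AX and nuclear-GFP counter assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    randomForest,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
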