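Package: gestewas
Title: Longitudinal Maternal Blood Methylation Analysis of Gestational Age at Birth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A paired-timepoint pipeline for epigenome-wide association analysis of
    gestational age at birth in maternal whole-blood DNA methylation. Provides
    reference-based deconvolution of twelve leukocyte subtypes with paired
    timepoint comparisons, isometric log-ratio compositional principal components
    as cell-composition covariates, robust (Huber) per-CpG regression with
    empirical-null inflation correction and Benjamini-Hochberg false discovery
    control, methylation-derived surrogate scores (IL-6, allostatic load), a
    contribution analysis for psychosocial and biological covariates,
    co-methylated region construction with region-level association testing,
    modality-based mQTL flagging, chromatin-state overrepresentation, and a
    term versus preterm contrast. A synthetic paired-cohort generator with
    recorded ground truth drives testing and calibration so no external data
    download is required.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
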