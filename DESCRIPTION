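Package: ctffr
Title: Coronary CT Segmentation, Surface Reconstruction and Reduced-Order
    Fractional Flow Reserve
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for functional assessment of coronary
    stenosis from CT angiography volumes. Generates synthetic contrast-enhanced
    phantoms of stenosed vessels, segments the lumen by a two-class
    clustering-threshold (within-class sum-of-squares) criterion with an
    interactive live-wire boundary extractor, reconstructs a watertight
    triangle surface by tetrahedral isosurface extraction, estimates the lumen
    radius profile, and evaluates fractional flow reserve (FFR = Ps/Pr) with a
    steady reduced-order hemodynamic model validated against Poiseuille's law.
    A cohort layer simulates SYNTAX-score stratified patient tables and
    provides the associated correlation, ANOVA, chi-square, diagnostic-accuracy
    and ROC/AUC analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
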