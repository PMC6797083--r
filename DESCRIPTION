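Package: uexm
Title: Quantitative Analysis for Expansion Microscopy of Microbes
Version: 0.1.0
Authors@R:
    person("uexm", "developers", email = "uexm@example.org", role = c("aut", "cre"))
Description: Simulation and quantification tools for expansion microscopy of
    microbes (uExM). Provides a seeded synthetic micrograph generator with
    exact ground truth (spherocylindrical cells, species-specific expansion,
    DNA-halo phenotypes, PSF blur and camera noise), a watershed-based cell
    segmentation pipeline, rod-shape morphometry (five-station cell width,
    length, aspect ratio), population statistics (expansion ratio with
    cluster-bootstrap SEM, width-based species classification, Gaussian
    mixture fitting, DNA-halo phenotype calling), and a confined-Gaussian-
    chain model of DNA translocation through cell-wall pores (free-energy
    profile, entropic barrier, critical chemical potential).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
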