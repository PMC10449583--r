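Package: dwivar
Title: Quality Control and Multi-Site Variability Statistics for Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for assessing the quality and reliability of diffusion-weighted
    MRI (DWI) acquired across several sites, vendors and sessions. Implements
    gradient-table and sidecar parsing, b0-anchored signal drift normalization,
    powder averaging, shell detection, resolution- and sampling-adaptive model
    configuration (spherical-harmonic order selection and multi-compartment
    parameter budgeting), a weighted-least-squares diffusion tensor fit with
    validation maps, SNR/CNR estimation from b0 volumes, the image intraclass
    correlation coefficient (I2C2) for test-retest reliability, and intra-subject,
    between-subject, intra-vendor and between-vendor coefficients of variation.
    A synthetic multi-site phantom generator with known ground truth makes the
    whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
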