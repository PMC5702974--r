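Package: myoarch
Title: Ventricular Myocardial Architecture from Diffusion Tensor
    Cardiovascular MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for mapping ventricular myocardial
    architecture from ex-vivo diffusion tensor cardiovascular magnetic
    resonance. Fits diffusion tensors by ordinary least squares on
    log-signals, constructs per-sector epicardial tangential-plane
    coordinate frames, computes voxel-wise helical, intrusion and E3
    (sheetlet-normal) angles with transmural depth, performs FACT
    streamline tractography over the primary eigenvector field, and
    compares angle distributions between groups with Kolmogorov-Smirnov
    and Mann-Whitney tests. A synthetic biventricular phantom generator
    with prescribed fibre and sheet-normal fields provides ground truth
    for validation and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
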