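Package: fbngan
Title: Adversarial Construction of Brain Functional Networks from 4D fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns region-of-interest (ROI) time series and brain functional
    connectivity networks directly from 4D fMRI volumes with an adversarially
    trained generator. A region-guided 3D convolutional network extracts rough
    per-ROI features conditioned on atlas geometry (ROI centers and volumes), a
    spatial-temporal attention module refines them into generated ROI time
    series, and a learnable Gaussian kernel maps the series to a connectivity
    matrix. A multi-channel temporal discriminator enforces agreement with
    empirical (toolbox-style) ROI series under a least-squares adversarial
    loss, and a graph convolutional classifier predicts diagnostic group from
    the (network, series) pair. Includes a synthetic fMRI phantom simulator
    with planted class-dependent connectivity, cross-validated evaluation,
    ROI-shielding importance ranking, and altered-connectivity group analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
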