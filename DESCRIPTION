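Package: thoraxAC
Title: Simulation of Attenuation-Correction Bias in Thoracic PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Digital-thorax simulation framework for studying how the
    attenuation map used in PET reconstruction biases standardized uptake
    values (SUV) in lung tissue. Generates reproducible thorax phantoms
    with a controllable anterior-to-posterior lung-density gradient and
    bone structures, builds four attenuation-map variants (CT-based,
    lung-LAC-replaced, additionally bone-stripped, and pure four-class
    segmentation), simulates attenuated Poisson emission data with a
    parallel-beam projector, reconstructs with ordered-subsets
    expectation maximization (OSEM), and quantifies regional SUVmean
    bias with an ROI scheme, relative-difference statistics, ANOVA with
    Bonferroni correction, and a mean-lung-density emphysema screen.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
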