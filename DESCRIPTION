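Package: gmatrophy
Title: Gray Matter Atrophy Rates from Serial MRI and Trial Sample Sizes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures longitudinal gray-matter and whole-brain atrophy from
    pairs of T1-weighted volumes using three techniques: nonlinear viscous-fluid
    registration with integration of Jacobian determinants over the gray-matter
    region, Gaussian-mixture tissue segmentation with subtraction of serial
    volumes, and the brain boundary shift integral.  Includes affine pairwise
    pre-processing (12-dof registration, tissue-based intensity normalisation,
    dilated-brain cropping), a three-tissue digital phantom generator with
    analytically known atrophy for validation, and the clinical-trial statistics
    layer: annualised rates, sample-size-per-arm estimation with and without an
    aging adjustment, effect-size and power rescaling, Pitman's paired test for
    equality of correlated variances, and bias-corrected accelerated bootstrap
    confidence intervals for sample-size ratios.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
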