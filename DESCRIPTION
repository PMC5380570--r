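Package: lungquant
Title: Quantitative Lung CT Aeration Analysis with Sparse-Slice Extrapolation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of lung aeration from computed tomography.
    Classifies lung voxels into hyper-, normally, poorly and non-aerated
    compartments from Hounsfield units, computes total lung volume and weight
    under the linear HU-density model, extrapolates whole-lung quantities from
    sparse equally spaced axial slices (sequential acquisitions) via a
    trapezoidal formula, validates the extrapolation against full spiral
    stacks with Bland-Altman agreement statistics, and compares radiation
    dose between spiral and sequential protocols. Includes a synthetic
    thorax phantom generator with analytic ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
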