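Package: tractometr
Title: Tractometry: Bundle Recognition, Along-Tract Profiles and Profile Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Recognizes white-matter bundles from a tractogram (TRK/TCK) using an
    ordered set of anatomical criteria (waypoint and endpoint ROIs, probability
    maps, midline crossing, length, primary travel axis, shape priors), cleans
    them with Mahalanobis and QuickBundles-threshold outlier removal, extracts
    Gaussian-weighted along-tract profiles of scalar maps (NIfTI) onto a fixed
    number of nodes, and analyzes profiles with point-wise group models under
    FDR correction, exponential learning-curve fits, and 1-D profile
    augmentation. Ships a synthetic streamline-phantom generator so the whole
    pipeline is testable without imaging data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
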