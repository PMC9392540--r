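Package: disconnectr
Title: Lesion Disconnectome Mapping and Brain-Behavior Partial Least Squares
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds voxel-wise structural disconnection probability maps from
    binary lesion masks and normative whole-brain tractograms, relates them to
    behavioral scores with nonrotated (contrast-driven) behavioral partial
    least squares including permutation significance and bootstrap-ratio
    (pseudo-z) maps, extracts suprathreshold clusters from the statistic maps,
    and correlates cluster disconnectivity with a cognitive battery. Ships a
    synthetic phantom-cohort generator with a planted disconnection-cognition
    effect so the full pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
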