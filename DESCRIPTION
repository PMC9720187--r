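Package: surflight
Title: Surface-Based Grid-Searchlight Multivariate Pattern Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Surface-space searchlight decoding of fMRI activity patterns on
    spherical cortical templates. Builds geodesic sphere templates by
    icosahedron subdivision, downsamples a high-resolution spherical template
    by nearest-vertex grouping, constructs rotation-based grid searchlights
    (an n1 x n1 image of cell-averaged BOLD values under a circular mask) at
    every downsampled vertex, decodes condition labels with leave-one-run-out
    cross-validated linear support vector machines (or a compact convolutional
    network), and performs group inference with a one-tailed t-test against
    chance followed by sign-flip max-cluster-size permutation correction for
    family-wise error. Includes a synthetic surface dataset generator with
    known ground-truth information patches, readers for paradigm files and
    surface-encoded NIfTI time series, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    parallel,
    e1071,
    RNifti,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
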