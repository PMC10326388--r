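Package: phmri
Title: Pharmacological MRI Activation Mapping and Resting-State Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacological MRI (phMRI) studies in
    small animals: synthetic 4D BOLD data with known ground truth, scan
    preprocessing (motion-outlier detection, detrending, Gaussian smoothing,
    band-pass filtering, nuisance regression, affine registration), voxelwise
    percent-change activation mapping with a rank-based false-positive
    filter, atlas-space composite maps, per-region volume-of-activation
    dose-response statistics (Kruskal-Wallis, exact Wilcoxon rank-sum),
    and atlas-parcellated resting-state functional connectivity with
    Fisher-Z edge statistics, thresholded graphs and degree-centrality
    group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    signal,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
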