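Package: metastate
Title: Prior-Free Detection of Brain Network Meta-State Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transitions between whole-brain network meta-states in
    fMRI network-activation timeseries without group priors or training data.
    Each run is repeatedly embedded into two dimensions with t-SNE, the squared
    Mahalanobis distance between successive embedded timepoints is averaged
    across repetitions into a step distance vector, and peak-prominence
    detection identifies transition timepoints while wide troughs mark
    meta-stable periods. Includes the validation machinery around the method:
    dual regression of spatial network maps, movie-feature alignment with a
    censoring cascade and hemodynamic-lag sampling, group conformity and
    trait-stability statistics (ICC(2,k)), bootstrap inference with bootstrap
    ratios, phase-randomized surrogates, alternative embedding baselines, a
    voxelwise conjunction analysis, and a synthetic cohort generator with
    planted meta-state structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    optparse,
    Rtsne,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
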