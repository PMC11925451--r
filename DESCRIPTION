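Package: laminarfmri
Title: Laminar and Columnar Analysis of Block-Design BOLD fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of cortical depth-dependent (laminar) and
    columnar fMRI experiments. Provides a synthetic-data generator that plants
    stripe-shaped columnar preference maps, depth-dependent response gains and
    block-level shared response variability on an abstract cortical sheet;
    ordinary-least-squares GLM fitting with a canonical block response;
    equi-volume cortical depth assignment and pial-vein exclusion; selectivity
    indices with laminar, eccentricity and stripe-compartment profiles;
    automated stripe segmentation; test-retest columnar pattern reliability
    with a Monte-Carlo family-wise-error null based on the spatial
    autocorrelation of GLM residuals; and layer-specific informational
    connectivity from leave-one-run-out max-margin decoding distances, with
    repeated-measures ANOVA, bootstrap and false-discovery-rate group
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
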