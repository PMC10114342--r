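Package: connectograd
Title: Connectopic Mapping and Trend-Surface Analysis of Functional
    Connectivity Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates spatially continuous functional-connectivity
    gradients (connectopic maps) of a region of interest from 4D BOLD
    fMRI: voxelwise connectivity fingerprints against a target mask,
    eta-squared similarity, k-nearest-neighbour graph construction, and
    Laplacian eigenmaps. Gradients are summarised by trend-surface
    models (polynomial spatial regression fit by evidence-maximised
    Bayesian linear regression), subjects are screened by
    explained-variance and gradient-direction quality control, and the
    resulting spatial coefficients are related to biomarkers, genotype
    and cognition through covariate-adjusted rank statistics with
    false-discovery-rate control. Includes a synthetic-data module that
    plants gradients, artifact subjects and coupled cohort tables with
    known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    igraph,
    jsonlite,
    readr,
    tibble,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    dplyr,
    ggplot2
Config/testthat/edition: 3
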