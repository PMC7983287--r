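Package: laflow4d
Title: Left Atrial 4D-Flow Hemodynamic Biomarkers and Reproducibility Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes global left atrial (LA) hemodynamic biomarkers from
    time-resolved three-directional (4D-flow) velocity fields: per-voxel peak
    and mean velocity, stasis (fraction of cardiac frames below a velocity
    threshold), volume-averaged vorticity and its cycle integral, lambda2
    vortex-core volumes, and rule-based pathline flow-pattern classification
    with 4th-order Runge-Kutta integration. Includes the velocity-data
    corrections the biomarkers require (temporal anti-aliasing unwrap,
    polynomial eddy-current offset removal, divergence-free Fourier
    projection), analytic 4D velocity phantoms with known ground truth,
    simulation of repeated-measures reproducibility studies, and the
    accompanying statistical toolkit: root-mean-square within-subject
    coefficient of variation with bootstrap confidence intervals and
    bootstrap comparisons of independent and dependent CVs, Bland-Altman
    limits of agreement and agreement-based power calculations, two-way
    mixed-model intraclass correlation, McNemar's test, stratified-bootstrap
    Pearson and Spearman correlation.
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
    igraph,
    jsonlite,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
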