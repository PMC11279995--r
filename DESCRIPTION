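Package: opivi
Title: Multi-Angle Hyperspectral Vegetation Indices and Angle-Stable LAI
    Estimation
Version: 1.0.0
Authors@R:
    person("opivi", "maintainers", email = "opivi@example.org",
           role = c("aut", "cre"))
Description: Tools for canopy hyperspectral reflectance observed at multiple
    view zenith angles in the solar principal plane. Computes 16 vegetation
    indices (15 established formulas plus the observation perspective
    insensitivity vegetation index, OPIVI), quantifies the angle sensitivity of each index
    (nadir-relative amplitudes, one-way ANOVA across angles, and the DR
    angular-stability statistic over correlation coefficients), and estimates
    leaf area index (LAI) by per-angle linear regression and multi-angle
    machine-learning regressors (random forest, gradient-boosted trees, and
    RBF support-vector regression). Includes Savitzky-Golay preprocessing, a
    long-format CSV interface, a synthetic multi-angle canopy generator with
    a kernel-style BRDF factor and Beer-Lambert gap fraction, and a staged
    command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    quadprog,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
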