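Package: plsdr
Title: Partial Least Squares Extensions of the Cox Model via Deviance Residuals
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits Cox proportional-hazards survival models in high-dimensional
    settings through partial least squares (PLS) regression on null-model
    deviance residuals, including sparse, group, sparse-group and kernel
    variants (PLSDR, sPLSDR, gPLSDR, sgPLSDR, DK*), together with the
    iterative PLS-Cox and autoPLS-Cox constructions. Provides censored-data
    cross-validation criteria (naive and van Houwelingen cross-validated
    partial likelihood, six integrated time-dependent AUC estimators, IPCW
    Brier and Schmid prediction-error curves), performance measures including
    the integrated R Schmid Score weighted (iRSSw), likelihood R-squared
    coefficients, Harrell, Uno and Gonen-Heller concordance, and three
    gene-expression survival simulators (eigengene, cluster, factorial) with
    calibrated exponential censoring and MCAR masking, so that criterion
    comparisons for component-number selection can be rerun at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, survival
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
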