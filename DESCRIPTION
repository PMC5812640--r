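Package: r1ratio
Title: Variable-Flip-Angle R1 Relaxometry and Longitudinal R1-Ratio Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative R1 (1/T1) relaxometry from spoiled gradient-echo
    images acquired at several flip angles, and a longitudinal analysis of
    radiotherapy-induced R1 change in brain tissue.  Provides the SPGR signal
    model and its linearized per-voxel fit, R1 map generation with validity
    masking, a seeded digital brain phantom with a radiation dose model,
    dose-stratified region-of-interest measurement of pre/post-radiotherapy
    R1 and R1 ratios, and the associated statistical battery
    (normality-gated two-sample tests, univariate and stepwise linear
    regression, intraclass correlation, Bland-Altman limits of agreement,
    MDRD eGFR and hepatic-function covariates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    nortest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
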