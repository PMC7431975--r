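Package: ihmtr
Title: Silent Inhomogeneous Magnetization Transfer Ratio Mapping and Repeatability Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes the five semi-quantitative magnetization transfer (MT)
    ratio maps (MTR, eMTR, MT asymmetry, ihMTR and inverse ihMTR) from the six
    weighted volumes of a silent zero-echo-time ihMT acquisition, and provides
    the downstream repeatability analysis: region-of-interest summary
    statistics, between- and within-subject coefficients of variation,
    ICC(2,1) estimation from a two-way random-effects model with
    gamma-regularized variance components and bootstrap percentile confidence
    intervals, and a head-orientation analysis that extracts rotation angles
    from affine transform chains and fits a linear mixed model for the angle
    effect on inverse ihMTR. A digital phantom simulator generates complete
    synthetic studies (weighted volumes, ground-truth transforms and truth
    tables) with Rician noise, subject and scan variance components and a
    linear head-angle effect, so every stage of the pipeline is testable
    without acquired data. Deterministic protocol arithmetic for the
    zero-echo-time sequence timing and saturation power is included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
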