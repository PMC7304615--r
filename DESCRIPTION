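Package: fsint
Title: Full-Stage Rank-Based Inverse Normal Transformation Association Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Single-variant association tests for quantitative traits under
    non-normal errors, centred on the fully adjusted full-stage rank-based
    inverse normal transformation (FS-INT) procedure: covariate residuals are
    rank-normalized and the residualize-then-transform step is iterated until
    the covariate effects on the transformed residuals are non-significant (or
    the coefficients stabilize) before the genotype is tested with a
    covariate-adjusted score test.  Seven comparator procedures are included
    (median regression, Yeo-Johnson power-transform regression, the plain
    score test, and the direct, indirect, omnibus, partly adjusted and fully
    adjusted two-stage INT tests), together with a Monte-Carlo simulation
    engine that estimates empirical type I error and power over scenario grids
    with confounded rare-variant genotypes, and readers for delimited
    phenotype/dosage tables and VCF genotypes.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    parallel,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    vcfR,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
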