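Package: fixelharm
Title: ComBat Harmonisation of Fixel-Based Analysis Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Empirical-Bayes ComBat harmonisation of fixel-based analysis
    (FBA) metrics (fibre density, log fibre cross-section, and their
    product) across acquisition sites, scanner models and imaging
    protocols. Reads and writes the NIfTI-1 fixel directory layout,
    fits the per-fixel location-scale batch-effect model with parametric
    empirical-Bayes shrinkage, and provides the accompanying evaluation
    statistics (percentage-difference maps, max-statistic permutation
    testing with family-wise error control, Cohen's d, tract means, and
    OLS regression with bootstrap confidence intervals) together with a
    synthetic fixel-data generator emulating travelling-subject and
    case-control multi-scanner designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    sva,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
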