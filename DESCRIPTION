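Package: binprofiler
Title: Negative-Control Binning Profiles for High-Content Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Subpopulation profiling of high-content screening data using
    negative controls only. Cell populations of every well are quantile-binned
    against the pooled per-plate DMSO distribution; per-bin occupancies are
    z-scored against the DMSO wells; "stable" parameters are selected by a
    per-well multinomial chi-square test on control wells; an L1-penalized
    multinomial logistic regression provides a supervised feature-selection
    baseline; profiles are classified into modes of action by cosine
    nearest-neighbor with leave-one-out evaluation. Includes a synthetic plate
    generator with planted stable, noisy, degenerate and phenotype-shifted
    parameters for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    graphics,
    stats,
    tools,
    utils
Suggests:
    arrow,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
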