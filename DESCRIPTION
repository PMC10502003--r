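Package: ensembleseg
Title: Label Fusion and Robustness Analytics for Ensembles of Organ
    Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Combines ensembles of candidate binary organ segmentations into
    consensus masks (probability averaging with thresholding, majority
    voting, STAPLE expectation-maximization, and pairwise-Dice regression
    model selection), scores segmentations against a reference with overlap
    and spacing-aware surface-distance metrics (Dice, relative volume
    difference, average and maximum symmetric surface distance), and
    quantifies ensemble robustness: percentile outlier boundaries,
    high-risk images, ensemble rescue rates, gain statistics with
    errors-in-both-variables (York) line fits, and ensemble-size
    subsampling experiments.  A deterministic synthetic-study generator
    produces ground-truth phantoms and simulated model outputs with
    boundary jitter and rare catastrophic failures, so the whole analysis
    can be exercised end-to-end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    oro.nifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
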