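Package: acpassf
Title: Uncertainty-Aware Augmented Sample Selection for Anticancer Peptide
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature-space data augmentation with uncertainty-aware selection
    of augmented samples for anticancer peptide (ACP) classification.
    Peptides are encoded as 400-dimensional descriptor vectors (binary
    profile, ordinal positional encoding, k-spaced amino acid group pair
    composition, amino acid composition, and mRMR-reduced physicochemical
    index features), augmented by masked multiplicative perturbation, and
    scored with Monte-Carlo-dropout pseudo-labels so that only low
    uncertainty, high confidence, label-consistent augmented samples enter
    retraining. Includes a seeded synthetic peptide generator, a fully
    connected classifier with dropout-enabled stochastic inference,
    stratified cross-validated comparison of baseline, traditional data
    augmentation and selection-based training, and a command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
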