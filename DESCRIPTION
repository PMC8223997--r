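Package: aeppi
Title: Protein-Protein Interaction Prediction with Class-Specific Autoencoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binary protein-protein interactions from primary sequence
    alone. Proteins are featurized with Conjoint Triad descriptors (343 ordered
    triples of seven physico-chemical amino-acid classes) concatenated with
    Autocovariance descriptors (lagged correlations of physico-chemical property
    scales along the sequence). Two autoencoders are trained, one on interacting
    pairs and one on non-interacting pairs, in one of three fully connected
    architectures (Joint-Joint, Siamese-Joint, Siamese-Siamese); a pair is
    classified by converting the two reconstruction losses into a closed-form
    interaction probability. Includes seeded synthetic data generation with a
    planted interaction signal, k-fold cross-validation with confidence
    intervals, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    optparse,
    rlang,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
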