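Package: foldvar
Title: Predicting the Effect of Amino Acid Substitutions on Protein Folding Rates
Version: 0.1.0
Authors@R: person("foldvar", "developers", role = c("aut", "cre"),
    email = "foldvar@example.org")
Description: Machine-learning prediction of how single amino acid
    substitutions change the folding rate of two-state folding proteins.
    Variants are represented by 1161 sequence-, structure- and
    conservation-derived features and scored either as a three-class label
    (folding rate decrease / no effect / increase, defined by a band of
    +/-0.15 on the natural-log rate change) or as a continuous prediction
    of the log rate change.  Includes a deterministic gradient-boosted
    decision tree engine, a class-balanced under-sampling voting ensemble,
    weighted-importance feature selection over repeated grouped
    cross-validation partitions, the full classification and regression
    metric suite (including the generalized squared correlation), a
    Shrake-Rupley accessible surface area routine, and a synthetic data
    generator that plants a known signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
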