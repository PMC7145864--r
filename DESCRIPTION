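Package: peprt
Title: Peptide Retention Time Prediction and Variant Peptide Quality Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Sequence-based prediction of peptide liquid-chromatography
    retention time (RT) with a convolutional / bidirectional-GRU regression
    network whose architecture is chosen by a genetic algorithm, adapted to
    individual LC-MS/MS runs by transfer learning and combined across the
    best architectures by interquartile-range filtered ensemble averaging.
    Companion tools implement peptide-level target-decoy false discovery
    rate estimation for proteogenomic variant peptides (global, separate
    and two-stage estimators), RT-error based quality evaluation of
    peptide-spectrum matches, and ground-truthed simulators for peptide
    retention behaviour and scored target/decoy match populations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
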