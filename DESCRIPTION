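Package: pharmref
Title: Referral-Graph Classification of Online Pharmacies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts whether an online pharmacy is legitimate or illicit from
    the web sites that link to it. Implements a referral rating prediction
    method (RRPM), which scores each referring web site by the mix of
    legitimate and illicit pharmacies it links to and aggregates those
    qualities into a backlink-weighted reliability score with a
    sensitivity-first decision threshold, and a referral-based K-nearest
    neighbour classifier (RKNN) over backlink count vectors. Includes a
    stratified cross-validation harness with accuracy, Cohen's kappa,
    sensitivity and specificity (with an explicit unknown/abstain category),
    a synthetic referral-ecosystem generator for testing at the scale of a
    real pharmacy screening study, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    caret,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
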