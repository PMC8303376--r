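Package: cranioflow
Title: Surgical Tool Detection and Workflow Phase Estimation for Open
    Cranial Vault Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multilabel detection of surgical tools in video frames and
    temporal estimation of the surgical workflow phase for open cranial
    vault remodeling (craniosynostosis correction). Provides the CranioNet
    convolutional network and a frozen-backbone transfer-learning head
    trained with binary cross-entropy and L1 regularization, per-frame
    thresholded detection logs (CSV), a phase-estimation algorithm based on
    smoothed per-phase tool-presence signals and sequential batch selection,
    exact-match multilabel evaluation metrics, and a deterministic synthetic
    scene and detection-log generator so the whole pipeline is testable
    without operating-room recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
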