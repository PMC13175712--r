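Package: cmrpower
Title: Robust-Design Capture-Recapture Estimation and Monitoring-Design Power
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Demographic estimation and monitoring design for
    capture-mark-recapture studies of sessile or slow-moving animals such as
    freshwater mussels. Implements a full-likelihood Pollock robust-design
    model (annual survival, first-capture and recapture probabilities,
    random or Markovian temporary emigration, abundance via the estimated
    number of never-captured individuals) with a declarative candidate-model
    grammar and AICc ranking; closed-population abundance estimators
    (Lincoln-Petersen index with Chapman correction, and the M0 maximum
    likelihood estimator); a population and capture-history simulator with
    known truth; and a simulation-based power analysis for detecting
    population declines under alternative numbers of within-season sampling
    occasions. Reads and writes Program MARK encounter-history (.inp) files
    and long-format CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
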