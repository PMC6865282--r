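Package: opichatter
Title: Toxicovigilance from Opioid-Related Social Media Chatter
Version: 0.1.0
Authors@R: person("Opichatter", "Maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for monitoring opioid abuse signals in
    short social-media texts: lexicon-driven retrieval with automatic
    spelling-variant expansion and noise-term filtering, four-class
    supervised classification (abuse, information, unrelated,
    non-English) with six classifier families, class-imbalance
    resampling including SMOTE, majority and minority-biased ensemble
    voting, imbalance-aware evaluation with bootstrap confidence
    intervals, and geotemporal aggregation of abuse-indicating post
    rates with correlation against regional reference health metrics.
    Includes a synthetic corpus generator with known ground truth so
    every stage is testable without access to restricted social-media
    data.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
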