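Package: painwatch
Title: Surveillance of Back-Pain Complaints in Social-Media Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An infodemiology pipeline for estimating changes in the frequency
    of first-person back-pain complaints between two time periods from a
    stream of short social-media posts. Provides JSON-lines corpus and CSV
    label input/output, a seed-deterministic synthetic two-period tweet
    simulator with configurable duplicate, language, artifact and annotator
    noise, text normalization (image/URL/retweet tokenization, character-run
    collapse, emoji naming), exact-text deduplication, nominal Krippendorff
    alpha inter-annotator agreement with unanimity/majority adjudication, a
    two-stage complaint classifier (pluggable text feature extractor feeding
    a gradient-boosted tree model) with stratified fivefold cross-validation,
    a full binary-classification metric suite (accuracy, balanced accuracy,
    macro/micro/weighted F1, Matthews correlation), and period-comparison
    statistics (Shapiro-Wilk normality, two-group one-way ANOVA, polynomial
    trend fits, percent-change reporting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    Matrix,
    stats,
    stringi,
    tibble,
    utils,
    withr,
    xgboost
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
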