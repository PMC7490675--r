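Package: sentistream
Title: Sentiment Surveillance Pipelines for Social-Media Text Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for opinion surveillance ("infoveillance") over long-running
    social-media text streams: filtering and deduplication of tweet-like
    corpora, monthly-stratified sampling, quality control of crowdsourced
    annotations (raw agreement, outlier screening, Fleiss' kappa, unanimity
    consensus), a relevance-gated classifier cascade with a multinomial
    bag-of-words baseline and macro-F1 evaluation, a rolling-window sentiment
    index with linear trend estimation and Welch tests of yearly means,
    topographic-prominence peak detection on activity series, and topical
    breakdowns by organism class, hashtag, and regex-defined themes. A
    synthetic corpus generator with known ground truth (drifting sentiment,
    event bursts, duplicates, noisy annotators) makes every stage testable
    without access to platform data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    sandwich,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
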