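Package: ddetect
Title: Zero-Shot Detection of Drug Discontinuation Events in Forum Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for detecting drug discontinuation events (DDEs) in
    web-forum comments with zero-shot natural-language-inference
    classification, and for classifying their root causes over a closed
    eight-category taxonomy. Provides sentence segmentation and
    token-budget chunking, three max-aggregation classification strategies
    over a pluggable entailment scorer, a multilabel root-cause layer, a
    full evaluation suite (confusion metrics, ROC/PR curves, hamming loss,
    Jaccard, subset accuracy, micro/macro/weighted averages), a
    deterministic mock scorer, and a synthetic forum-corpus generator so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
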