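Package: tesar
Title: Explicit Semantic Analysis in Title Space for Semantic Relatedness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distributional semantic relatedness over a title+body document
    corpus. Implements Explicit Semantic Analysis (ESA), which represents a
    free-text input as a truncated vector of its tf-idf cosine scores against
    every document in a background corpus, and its title-space variant (tESA),
    which re-expresses that document vector in the much smaller vocabulary of
    document titles through a sparse term-by-document title matrix. Ships the
    accompanying evaluation protocol (Spearman rank correlation against human
    consensus ratings, coverage recall, agreement-stratified sweeps, and
    confidence intervals for differences between dependent overlapping
    correlations) together with a seeded synthetic corpus and benchmark
    generator with planted topic structure, so the whole pipeline is testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
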