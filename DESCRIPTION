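Package: resdict
Title: Resilience Dictionary Construction from Peer-Support Forum Posts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A semiautomatic four-phase pipeline that turns a time-stamped
    corpus of peer-support forum posts into a resilience dictionary.
    Posts are deidentified, tokenized and lemmatized, assigned to calendar
    quarters, and converted to per-window TF-IDF matrices; a two-layered
    nonnegative matrix factorization discovers window-level base topics and
    corpus-level ensemble topics, with the ensemble size selected by
    embedding-based topic coherence. A human-supplied topic-to-indicator
    mapping annotates every post with resilience indicators (social capital,
    belonging, learning, adaptive capacity, self-efficacy); indicator
    prevalence is tracked per quarter, a subsumption taxonomy is inferred
    from indicator co-occurrence, and the dictionary is assembled with topic
    weights, top terms, and word-embedding synonyms. Includes a synthetic
    corpus generator with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
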