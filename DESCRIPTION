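Package: nlelp
Title: Analogical Reasoning for Mining Negative Life Event Language Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mining negative-life-event language patterns
    (<subject:action> pairs such as <parent:divorce>) from tokenized text
    corpora by analogical reasoning. Builds three distributional word
    representations (a hyperspace-analog-to-language co-occurrence space,
    a positive pointwise mutual information association matrix, and
    CBOW/skip-gram embeddings trained by negative sampling), scores
    candidate actions for analogy queries <alpha:beta>::<alpha*:?> under
    four inference engines (additive cosine, multiplicative cosine,
    HAL information inference, and raw PPMI induction), and evaluates
    ranked retrieval with mean reciprocal rank and precision-at-n over
    within-category and across-category query subsets. Includes a
    synthetic-corpus generator that plants recoverable subject-action
    structure for end-to-end benchmarking, and a command-line interface
    for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    optparse,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
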