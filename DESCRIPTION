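Package: hallmarker
Title: Hallmarks-of-Cancer Sentence Classification and Literature Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical multi-label classification of biomedical-literature
    sentences into a 37-class Hallmarks-of-Cancer taxonomy, and association
    analytics over the classified collection. Implements the full pipeline:
    MEDLINE/PubMed XML and annotated-corpus TSV parsing, seven sentence feature
    types with per-class feature selection, a joint word-label embedding for
    semantic-distance features, one-vs-rest linear support vector machines with
    inverse-proportional class weighting and hypernym label propagation,
    parent-favoring hierarchy-consistent post-processing, nested cross-validated
    evaluation with leave-one-out feature ablation and Cohen's kappa, and
    query-association statistics (conditional probability, PMI, NPMI,
    Fisher-exact/chi-squared testing with Bonferroni correction). A seeded
    synthetic-corpus generator emulating the statistical structure of the
    annotated corpus makes every component testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
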