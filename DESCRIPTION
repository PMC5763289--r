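Package: symkb
Title: Construction of a Symptom-Centric Medical Knowledge Base from
    Heterogeneous Chinese Sources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for building a symptom-centric medical
    knowledge base in Chinese: wrapper-based extraction of entities and
    attribute-value pairs from healthcare-site detail pages, seed-category
    bootstrapping and decision-tree classification of encyclopedia entities,
    conditional random field (CRF) recognition of symptom mentions in
    electronic medical record text, entity fusion by longest-common-subsequence
    name similarity combined with shared-fact relatedness, cross-lingual
    linking of symptoms to an English concept table via translation and exact
    Jaccard matching of word bags, and export of the resulting knowledge base
    as Linked Data (Turtle / N-Triples).  Deterministic synthetic-data
    generators with planted ground truth emulate every input the pipeline
    consumes, so the full system runs and is evaluated without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    rpart,
    stats,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
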