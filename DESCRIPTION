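Package: asmnet
Title: Differential Co-Expression Network Analysis of Two-Condition
    RNA-Seq Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to contrast gene co-expression networks between two
    biological conditions (e.g. diseased vs healthy tissue) from bulk
    RNA-seq counts. Provides CPM-based expression filtering and a
    linear-model differential-expression stage; regulatory impact factor
    (RIF1/RIF2) scoring of transcription factors against differentially
    expressed genes; co-expression network inference with the partial
    correlation and information theory (PCIT) trio-elimination algorithm;
    hub detection by the mean + 2 SD degree rule and scale-free topology
    fits; union (central reference) networks with standardized
    differential connectivity (DK) z-scores for rewiring calls; Fisher
    z-tests of per-pair correlation differences with the nine-class
    (+/-/0 per condition) taxonomy; hypergeometric over-representation
    analysis of user-supplied gene sets with Cohen-kappa grouping of
    redundant terms; and a negative-binomial count simulator with planted
    differential expression, planted TF-centred co-expression modules and
    planted rewiring, so every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
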