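Package: chicogs
Title: Statistics for Promoter Capture Hi-C Interactomes and GWAS Gene
    Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the statistical analysis of promoter capture Hi-C
    (PCHi-C) interactomes across cell-type panels: cell-type specificity
    scores for interactions, clusters and genes; distance-matched
    randomization of promoter-interacting regions (PIRs) for chromatin
    feature enrichment; overdispersion-adjusted contingency tests for
    enhancer-promoter activity coupling; directionality-index TAD calling;
    eQTL-PIR overlap with LD expansion and bait-shift randomization; GWAS
    summary-statistic preparation including LD-proxy p-value transfer;
    single-causal-variant fine mapping via approximate Bayes factors; the
    COGS gene prioritization score; a TAD-based baseline score; and the
    blockshifter rotation-permutation tissue-set enrichment test. A
    synthetic-data generator produces all inputs with the planted structure
    the analyses assume, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
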