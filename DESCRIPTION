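Package: ipscvar
Title: Variance Decomposition and Reprogramming-Outcome Classification for
    iPSC RNA-seq Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline for dissecting transcriptional heterogeneity
    among human induced pluripotent stem cell (iPSC) lines derived from
    multiple somatic tissues of multiple donors. Implements a pooled linear
    mixed model that decomposes log2 FPKM variation into cell-class,
    tissue-of-origin, donor and sequencing-batch variance components (with
    homoscedastic and heteroscedastic residual structures), a five-hypothesis
    negative-binomial classification of reprogramming outcomes (invariant,
    correctly reprogrammed, transcriptional memory, aberrant, complex) with
    permutation false discovery rates and a hierarchical mixture model for
    category proportions, a beta-binomial isoform-ratio analogue, phased
    allele-specific expression and imprinting analysis, and replication tests
    for externally ascertained eQTLs. A synthetic-data generator emulating the
    full study design provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
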