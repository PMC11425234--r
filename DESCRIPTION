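Package: masldstage
Title: Transcriptomic Staging of MASLD from Severity-Associated Gene Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a liver-disease severity gene signature from multi-cohort
    bulk RNA-seq with histology covariates (NAS and fibrosis stage), scores
    individual samples by single-sample gene-set enrichment (ssGSEA), and maps
    query mouse samples onto the human severity scale through ortholog-linked
    signatures. Implements per-gene negative-binomial GLMs with ordinal
    severity covariates, Boruta shadow-feature selection, median-of-ratios
    normalization with a closed-form variance-stabilizing transformation, and
    rank-based cross-species severity mapping. Includes a synthetic multi-cohort
    count generator with known ground truth so every stage is verifiable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger
Suggests:
    testthat (>= 3.0.0),
    MASS,
    DESeq2,
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
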