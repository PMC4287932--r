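Package: emtscore
Title: Quantitative EMT Scoring and Signature Derivation from Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the epithelial-mesenchymal transition (EMT) status of
    transcriptomic samples on a continuous [-1, +1] scale using a signed
    two-sample Kolmogorov-Smirnov statistic computed on the rank empirical
    cumulative distribution functions of epithelial and mesenchymal gene
    sets. Also provides the signature-derivation machinery: single-sample
    gene set enrichment (ssGSEA) pre-ranking, SVD-metagene probit phenotype
    prediction, extreme-sample selection, SAM permutation q-values and
    per-gene ROC marker selection, and a weighted cross-cancer combination
    of disease-specific signatures into a generic EMT signature. A
    synthetic-cohort generator with a planted EMT axis makes every stage
    testable without external cohorts. Readers and writers for TSV/GCT
    expression matrices, GMT gene sets and signature tables are included,
    together with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
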