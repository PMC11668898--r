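Package: radresist
Title: Comparative Radioresistance Analysis of Paired Tumour Cell Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An integrated pipeline for characterising acquired radioresistance
    in paired irradiated/parental cancer cell-line models and relating it to
    patient outcome. Implements consensus somatic SNV calling across multiple
    callers and replicates with 96-trinucleotide-context mutation catalogues,
    COSMIC-style SBS signature refitting by iterative forward selection with an
    overfit guard for sparse catalogues, a simplified negative-binomial Wald
    test with direction-consistent intersection of differentially expressed
    genes across cell lines and hypergeometric over-representation analysis,
    single-sample gene-set enrichment (ssGSEA) scoring, survival stratification
    by a stepwise quantile cutoff scan with Kaplan-Meier, log-rank and Cox
    analyses, and radiobiology assay statistics (linear-quadratic clonogenic
    fits, foci summaries, kernel-density tail probabilities, delta-delta-Ct
    fold changes). A seeded synthetic-data module generates every pipeline
    input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    DESeq2,
    S4Vectors
Config/testthat/edition: 3
RoxygenNote: 7.3.3
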