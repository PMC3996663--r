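Package: lncseek
Title: Discovery and Biomarker Characterization of Long Non-Coding RNAs
    from Paired Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a long non-coding RNA
    (lncRNA) discovery and characterization pipeline for paired
    metastatic/non-metastatic transcriptomes: RPKM quantification with
    per-sample root-mean-square normalization, biotype/length catalog
    filtering, paired fold-change calling, coding-potential assessment by
    six-frame ORF scanning and the Fickett TESTCODE statistic, derivation
    of an anchor-gene-associated expression signature by top/bottom-k
    dichotomization with a Significance Analysis of Microarrays (SAM)
    permutation d-statistic, concept gene-set enrichment (one-sided
    hypergeometric test with odds ratios), and relative quantification of
    qPCR data by the 2^-ddCt method with dual endogenous controls. A
    synthetic-data module generates every input with planted ground truth
    so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate: 
    'catalog.R'
    'enrichment.R'
    'fickett.R'
    'lncseek-package.R'
    'orf.R'
    'pipeline.R'
    'qpcr.R'
    'quant.R'
    'reexports.R'
    'signature.R'
    'sim-config.R'
    'simulate.R'
    'utils.R'
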