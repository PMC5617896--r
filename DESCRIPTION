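Package: facreg
Title: Regulon Inference from Factorial Transcription-Factor Deletion
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring combinatorial transcription-factor
    dependencies from factorial deletion-strain RNA-seq experiments, as used
    to dissect the GaaR/AraR/RhaR pectinolytic regulatory network of
    Aspergillus niger. Provides FPKM quantification and expression-status
    calling, a self-contained negative-binomial Wald test with
    median-of-ratios normalization and Benjamini-Hochberg correction,
    classification of per-genotype regulation patterns into minimal monotone
    Boolean (DNF) dependency expressions with predominant-activator
    attribution, Venn partitioning and temporal-switch detection,
    deterministic complete-linkage hierarchical clustering, promoter motif
    machinery (IUPAC and PWM scanning with exact dynamic-programming
    p-values, ZOOPS-EM motif discovery, Fisher enrichment, cross-species
    conservation), and a negative-binomial synthetic-data generator with
    known regulatory ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
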