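Package: vitreomics
Title: Vitreous Humor Proteomics Signatures from Label-Free Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for two-group vitreous humor (or other body
    fluid) label-free proteomics. Normalizes iBAQ-style protein intensities
    to iFOT fractions, partitions proteins by group-wise detection, tests
    shared proteins for differential abundance with Benjamini-Hochberg FDR
    control, defines up/down protein signatures, validates signatures on
    independent cohorts by mean Z-score with one-tailed Mann-Whitney tests
    and ROC/AUC, and infers upstream transcription factors by Fisher exact
    over-representation of GMT target sets and by gene set enrichment
    analysis (weighted running-sum enrichment score with permutation
    significance and normalized enrichment scores). Includes a synthetic
    cohort generator with abundance-dependent detection dropout and planted
    ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cli,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
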