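Package: aied
Title: Differential A-to-I RNA Editing Analysis from Allele Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for transcriptome-wide adenosine-to-inosine (A-to-I) RNA
    editing analysis starting from per-site allele-count tables: orientation
    and validation of A-to-G candidate sites, known-site flagging and repeat
    annotation, high-confidence site cataloguing, editing-level
    quantification, differential RNA editing detection by binomial GLM
    likelihood-ratio tests with pooled-allele Fisher exact confirmation and
    Benjamini-Hochberg FDR control, age and sex covariate testing, temporal
    trend classification, TPM normalisation and cis-regulatory
    editing-expression correlation, cross-dataset overlap comparison, and
    treatment-rescue calling. Includes a beta-binomial synthetic-study
    generator with known ground truth for calibration and power analysis.
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
    IRanges,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
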