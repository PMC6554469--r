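Package: meictools
Title: Rank-Fraction Differential Expression and Semi-Quantitative IHC
    Scoring for Meiotic Cancer/Testis Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing ectopic expression of meiosis-specific
    cancer/testis (meiCT) genes in cutaneous T-cell lymphoma cohorts.
    Converts TPM expression matrices to within-sample rank fractions so
    that independently processed RNA-Seq cohorts can be pooled, tests
    case/control differences in mean rank fraction with a pooled-null
    bootstrap and Bonferroni correction, scores immunohistochemistry
    observations with a semi-quantitative percentage-by-intensity scheme,
    and compares score bands across disease stages with an exact
    Freeman-Halton r x c test computed by complete enumeration. A
    synthetic-data module generates expression matrices and IHC
    observation tables with known ground truth for validation.
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
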