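Package: metscreen
Title: Matched-Trio Screening for Metastasis-Associated Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for screening metastasis-associated genes in
    matched tumor (T), adjacent non-tumor (N) and metastatic lymph-node (LN)
    expression trios. Each gene is classified per patient case by fold-change
    rules (up: LN at least 2-fold above both T and N with T above N; down:
    N above T with LN at or below 0.5-fold of N and 0.8-fold of T), recurrent
    genes are selected by a k-of-n rule across cases, and leading genes are
    ranked by recurrence and median fold change. Downstream stages provide
    hypergeometric over-representation of gene sets with Benjamini-Hochberg
    control, immunohistochemistry score binning and group comparison,
    lymph-node-ratio stratification, Kaplan-Meier/log-rank survival analysis
    and marker correlations. A negative-binomial simulator of the matched-trio
    design with spiked ground-truth genes and linked clinical tables supports
    benchmarking of sensitivity and false discovery.
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
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
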