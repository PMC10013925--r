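Package: pvalqc
Title: Quality Control, Classification and Pi0 Estimation for
    Differential-Expression P-Value Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Diagnoses the quality of p-value sets produced by
    high-throughput sequencing differential-expression analyses. Mines
    p-value, adjusted-p and expression-level columns out of heterogeneous
    processed-data tables, classifies p-value histograms into five
    distributional classes with a Bonferroni-corrected binomial
    peak-detection threshold, estimates the proportion of true null
    hypotheses (pi0) by a rank-based local-FDR method and by Storey's
    smoother, and quantifies how removing low-count features rescues
    malformed p-value distributions. Ships negative-binomial count and
    p-value mixture simulators with known ground truth so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    tools,
    withr
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
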