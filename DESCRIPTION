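Package: gtindex
Title: Gene Tissue Index and Comparator Statistics for Cancer Outlier
    Gene Detection
Version: 0.1.0
Authors@R:
    person("gtindex", "maintainers", email = "gtindex@example.org",
           role = c("aut", "cre"))
Description: Detects cancer outlier genes, i.e. genes over-expressed in
    only a subset of disease samples, from two-group expression matrices.
    Implements the Gene Tissue Index (GTI), a Sen-poverty-index-style
    score combining the proportion of samples above a robust
    q75 + IQR cut-off with their mean relative exceedance, alongside four
    comparator statistics (pooled two-sample t, COPA, the Outlier Sum and
    the Outlier Robust t-statistic), permutation p-values, a simulation
    and ROC benchmarking engine, and method-comparison diagnostics for
    integrated multi-study matrices with per-gene missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
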