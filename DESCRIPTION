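Package: methylsel
Title: Gene-Centric Probe Selection for 450K DNA Methylation Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Selects, for each gene, the subset of Illumina 450K methylation
    probes most predictive of the gene's discretized (up/down) expression.
    Implements a sequential forward selection wrapper around pluggable
    classifiers (KNN, decision tree, kernel naive Bayes, SVM), alternative
    selectors (Gaussian-kernel SVM-RFE, ReliefF, a GA-KNN hybrid), random and
    top-two-correlated controls, and expression-agnostic selectors based on
    manifest annotation (upstream CpG islands, TSS windows, top standard
    deviation). Selections are assessed by leave-one-out cross-validation with
    confusion-based metrics including the Matthews correlation coefficient,
    and gene lists stratified by MCC can be compared with an exact
    hypergeometric overlap test. A seeded synthetic-data generator with
    planted informative probes makes the whole pipeline testable without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
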