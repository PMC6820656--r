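Package: mirvuln
Title: Network-Vulnerability Discovery of Chemoresistance miRNA Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a knowledge-guided network-vulnerability pipeline for
    discovering miRNA biomarkers of platinum chemoresistance from paired
    miRNA/mRNA expression profiles: empirical-Bayes moderated differential
    expression, extraction of the condition-specific bipartite miRNA-mRNA
    regulatory subnetwork, topology analysis (degree, betweenness, closeness,
    hub and bottleneck sets, power-law degree-distribution fit), the per-miRNA
    number-of-single-line-regulations (NSR) vulnerability statistic with a
    degree-preserving rewiring permutation null, a resistance-gene knowledge
    filter (NPRG), biomarker selection, and downstream evaluation by ROC/AUC
    and Kaplan-Meier/log-rank survival analysis.  A seeded synthetic-data
    generator emulates the statistical structure of the restricted patient
    cohorts so the whole pipeline can be exercised and calibrated at desk
    scale.
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
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    limma,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
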