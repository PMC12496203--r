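Package: combiphen
Title: Emergent Phenotypes and Transcriptional Synergy in Ligand-Combination Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking combinatorial ligand (microenvironmental)
    perturbations to cellular phenotype. Computes track-derived phenotype metrics
    (T0-normalised cell count, mean-squared-displacement motility, Clark-Evans
    nearest-neighbour ratio, cytoplasmic area) and a four-dimensional phenotypic
    response magnitude; tests for emergent combination phenotypes against the
    Highest Single Agent (HSA) expectation with ANOVA/Tukey/Dunnett statistics;
    counts differentially expressed genes, clusters treatment-response gene
    modules with gap-statistic K selection, fits an additive expression null for
    combinations and calls positively/negatively synergistic genes under the HSA
    rule; fits per-phenotype PLS1 (NIPALS) regressions with leave-one-out RRMSEP
    component selection, Variable Importance in Projection (VIP) scores and
    +/- gene signatures; and validates signatures against gene-essentiality
    tables and external expression datasets. Includes negative-binomial count and
    Brownian-track simulators with ground-truth records so every stage is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    matrixStats,
    multcomp,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
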