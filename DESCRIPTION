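Package: clrperm
Title: Compositional Permutation MANCOVA/ANCOVA for Mucosal Microbiota
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Permutation-based association analysis of mucosal microbiota
    composition with host phenotype, genotype and clinical covariates.
    Taxon counts binned into phylum/subphylum categories are centered
    log-ratio transformed and analysed by a distance-based permutation
    MANCOVA (Gower-centered Euclidean distances, sequential sums of
    squares, pseudo-F) with forward stepwise term selection over main
    effects and first-order interactions, per-category and
    empirical-logit qPCR permutation ANCOVAs, a repeated-measures
    permutation ANCOVA across sequencing platforms, cohort summary
    tests, and Benjamini-Hochberg false-discovery-rate control. A
    Dirichlet-multinomial synthetic-cohort generator reproduces the
    study design the analysis assumes so the full pipeline is testable
    without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
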