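Package: placentaMiR
Title: Demographic Drivers of miRNA Expression Variation in the Human Placenta
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting demographic drivers of small-RNA expression
    in bulk tissue, modeled on population studies of the human placenta.
    Implements count filtering, log2 quantile normalization, batch-effect
    removal and PCA outlier flagging; sequential (Type-I) ANOVA variance
    partitioning by eta-squared across demographic variables; differential
    expression by population and newborn sex with a permutation-calibrated
    null for the count of significant features; pooled-SD pairwise population
    tests with Benjamini-Hochberg correction; co-expression clustering of
    differentially expressed miRNAs; neighbor-joining dendrograms of
    population mean expression compared against Fst genetic distances by a
    Mantel test; the tau tissue-specificity index; table-driven evolutionary
    age assignment; hypergeometric category enrichment; miRNA-target
    repression tests; and imprinted-cluster correlation analysis against
    maternal anthropometry. A seeded negative-binomial simulator generates
    full study-shaped data bundles with known truth labels for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    limma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
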