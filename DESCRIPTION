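Package: fuseDE
Title: Integrated Differential Expression Analysis with P-Value Combination
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Runs four statistically distinct differential-expression engines
    (a negative-binomial exact test, a precision-weighted moderated t, a
    negative-binomial Wald test with trended dispersion shrinkage, and a
    variance-component score test, plus a Wilcoxon rank-sum alternative) on a
    single raw count matrix, and fuses their per-gene p-values with six
    combination methods (Lancaster, Fisher, Stouffer, Wilkinson,
    Bonferroni-Holm, Tippett) and a Max-P intersection rule. Includes three
    low-expression filters, TMM and median-of-ratios normalization, Cook's
    distance outlier screening, a negative-binomial count simulator with
    truth labels and outlier injection for benchmarking, confusion-matrix
    scoring (sensitivity, specificity, F1, MCC), diagnostic plots, and a
    narrated run report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    limma,
    DESeq2,
    optparse
biocViews: RNASeq, DifferentialExpression, GeneExpression, Normalization,
    MultipleComparison
Config/testthat/edition: 3
RoxygenNote: 7.3.3
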