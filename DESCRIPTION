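Package: placentex
Title: Layered Placental Transcriptome Analysis with Maternal-Fetal
    Deconvolution, Sex-Stratified Differential Expression, and
    Co-Expression Module-Trait Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for population comparisons of multi-layer placental
    RNA-seq cohorts. Estimates the maternal versus fetal origin of each
    dissected placental layer from allele-specific read counts at
    informative SNPs; performs per-layer, covariate-adjusted
    negative-binomial differential expression between populations,
    combined and stratified by infant sex; builds weighted gene
    co-expression modules, correlates module eigengenes with population
    membership and newborn traits using an effective-number-of-traits
    Bonferroni threshold, and flags significantly differential modules and
    their hub genes; and tests differentially expressed genes for
    over-representation of a selection-nominated gene panel by permutation
    with an exact hypergeometric cross-check. A synthetic-cohort generator
    with full ground truth (genotypes, allele-specific counts, layered
    count matrices, newborn traits) makes every stage testable without
    access to the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    DESeq2,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
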