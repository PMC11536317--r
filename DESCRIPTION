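Package: QTLValidate
Title: Validation of QTLs by LD-Window Matching in MAGIC Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess the reliability of previously reported quantitative
    trait loci (QTLs) before their use in marker-assisted or genomic selection.
    Implements the full validation pipeline for multiparent advanced generation
    intercross (MAGIC) recombinant inbred populations: simulation of
    eight-founder MAGIC RIL genotypes, testcross hybrids, and lattice-design
    field phenotypes; estimation of best linear unbiased estimators (BLUEs),
    REML variance components, and family-mean heritability; a kinship-corrected
    mixed linear model association scan with variance components estimated once
    on the null model (P3D); pairwise linkage-disequilibrium r-squared; and a
    two-criterion SNP/QTL validation rule (same SNP significant at p < 0.02, or
    a significant SNP within a +/- 2 Mbp window in LD r-squared > 0.2) applied
    across inbred and hybrid validation sets, with cross-set concordance
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Matrix,
    lme4,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
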