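Package: cssltools
Title: Genetic Dissection of Chromosome Segment Substitution Line Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs donor introgression segments in chromosome segment
    substitution line (CSSL) populations from two kinds of evidence: SSR
    graphical genotypes (the marker map, with the DD/DR/RR 100/50/0 percent
    length estimator) and whole-genome re-sequencing SNPs (a sliding-window
    recombination bin map). Provides genome coverage and density statistics,
    partitioning of population segments into non-overlapping blocks, a
    block-based stepwise likelihood-ratio QTL scan reporting LOD, percentage
    of variance explained and additive effects, multi-environment phenotype
    statistics (BLUPs, broad-sense heritability, Pearson correlations) and a
    weighted mean of additive effects (WAF). A synthetic CSSL population
    generator with known ground truth makes every stage testable.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    lme4,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
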