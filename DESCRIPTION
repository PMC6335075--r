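Package: carballoc
Title: Trio Introgression Mapping, Co-Expression Modules and T6P Signatures
    for Stem Sugar Accumulation
Version: 0.1.0
Authors@R:
    person("carballoc", "maintainers", email = "carballoc@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis of a breeding trio (two parents and a
    conversion line) to dissect stem sugar accumulation. Classifies
    RNA-seq-derived homozygous SNPs by parental origin, paints the genome
    in fixed-width bins and calls introgression segments, detects
    genotype-wise co-expression modules with eigengenes and permutation
    preservation, tests directional hypergeometric enrichment against
    trehalose-6-phosphate (T6P)/SnRK1-regulated gene sets, correlates gene
    profiles with a T6P metabolite signal, and applies a stringent
    candidate-gene filter (introgressed, differentially expressed,
    T6P-correlated, trend-discordant). Ships a fully parameterised
    synthetic-data generator that emulates the trio design with known
    ground truth, plus metabolome-side statistics (median normalization,
    PCA, ANOVA with Tukey compact letters, Welch tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
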