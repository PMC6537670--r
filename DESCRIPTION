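Package: msynet
Title: Male-Specific Y Haplotype Networks from Sexed Read Depth and Haploid Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for paternal-lineage analysis on a male-specific Y (MSY)
    draft assembly without a finished Y reference. Classifies fixed-width
    assembly windows into single-copy Y, multi-copy Y and non-Y classes from
    normalized male versus female read depth; filters haploid variant calls
    down to single-copy regions; collapses samples into haplotypes and builds
    a median-joining network with mutation-labeled edges; computes nucleotide
    diversity (pi) and Watterson's theta for sample subsets; and dates network
    nodes with the rho statistic and its standard error. A synthetic-data
    module simulates sexed coverage over a labeled genome template and
    haplotypes evolving on a known tree, providing full ground truth for
    recovery tests and an exhaustive Steiner-tree oracle for the network
    algorithm.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    igraph,
    jsonlite,
    vcfR,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
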