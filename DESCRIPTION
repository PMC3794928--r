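Package: methatlas
Title: Whole-Genome Bisulfite Methylome Analysis for Sparsely Methylated
    Insect Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for CpG methylome analysis of sparsely
    methylated genomes of the kind found in hymenopteran insects: simulation
    of genomes, methylomes and bisulfite reads with realistic study structure;
    strand-specific C-to-T converted reference construction and
    bisulfite-aware ungapped read placement; per-cytosine methylation
    reports with spike-in based conversion-efficiency estimation; CpG island
    and methylated-CpG-cluster detection; gene-body methylation status
    calling and metagene profiles; permutation statistics for spatial
    clustering of methylated genes; expression integration (tiling-array
    normalization, expression variation, Hartigan dip test, alternative
    splicing); and comparative statistics for ortholog conservation,
    cross-species concordance and paralog methylation loss.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    jsonlite,
    limma,
    methods,
    stats,
    tools,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
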