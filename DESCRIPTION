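Package: clonotyper
Title: Clonal SNV Genotyping, Chimera Inference and Genotype Relationships
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying and exploiting single-nucleotide variants
    (SNVs) that distinguish clones of a vegetatively propagated cultivar.
    Implements a hard-filter cascade for multi-clone variant calls (repeat
    mask, spurious-allele rule, recalibrated quality thresholds, and a
    discordant-read rule for homozygous calls), genotype-concordance
    partitioning of sites into varietal and clone-specific sets, transcript
    effect annotation with impact classes, inference of cell-layer (L1/L2)
    genotypes from tissue allelic fractions to detect periclinal chimeras,
    multilocus genotype classification of accession marker panels with
    minimal discriminating marker-subset search, and genotype-relationship
    reconstruction via allele-sharing distances, bootstrapped UPGMA
    dendrograms and median-joining networks. A synthetic-data module
    generates miniature genomes, annotations, multi-clone VCFs with planted
    truth, marker panels and tissue assays for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    igraph,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
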