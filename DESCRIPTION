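Package: tRNAcharge
Title: Aminoacylation-State Inference from Charged tRNA-Seq and
    Coverage-Based Expression Assessment of Transferred Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of periodate-protection ("charged") tRNA-seq
    experiments: reference handling with collapsing of identical gene
    copies, end-aware semi-global read alignment, 3' tail classification
    (intact CCA, single-nucleotide loss, deeper truncation, and CA-tail
    variants at C-discriminator genes), per-tRNA aminoacylation
    estimation with spike-in validation, modification-induced
    misincorporation profiling, and unique-read expression
    quantification. Also provides strand-specific mRNA-seq coverage
    statistics that rank a genomic region's depth against the intergenic
    background, used to assess whether horizontally transferred genes
    are transcribed. A simulator of the periodate chemistry and common
    tRNA-seq artifacts supplies ground-truth data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'reference.R'
    'align.R'
    'tails.R'
    'charging.R'
    'coverage.R'
    'expression.R'
    'profile.R'
    'simulate.R'
    'pipeline.R'
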