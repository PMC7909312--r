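Package: SRNaseScreen
Title: Screening and Genetic Validation of S-RNase Candidates in
    Gametophytic Self-Incompatibility
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering pistil S-RNases, the female determinant
    of gametophytic self-incompatibility (GSI), among T2 ribonuclease
    candidates from style transcriptomes. The package screens candidates by
    sequence features (isoelectric point, molecular weight, conserved CAS
    histidines), classifies them into T2 RNase classes I-III by p-distance
    against labelled references with neighbor-joining trees, flags
    low-polymorphic subclusters, infers exon/intron structure by exact
    spliced mapping of a CDS onto its genomic sequence, calls
    pistil-specific expression and 2^-ddCt fold changes, and simulates
    semi-compatible GSI crosses with S-linked and unlinked markers to test
    1:1 / 3:1 segregation by chi-square and assign S-haplotype roles. A
    synthetic-data module generates every input with known ground truth so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'SRNaseScreen-package.R'
    'align.R'
    'cli.R'
    'cluster.R'
    'constructors.R'
    'expression.R'
    'features.R'
    'gene-structure.R'
    'gsi.R'
    'io.R'
    'orf.R'
    'pipeline.R'
    'synthetic.R'
    'tree.R'
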