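Package: svclique
Title: Structural Variant Calling from Long-Read Alignments by Clique
    Clustering of SV Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects structural variants (>= 50 bp) from long-read
    SAM/BAM alignments. Signatures of structural variation are collected
    from within alignments (large CIGAR gaps) and between the split
    alignment segments of chimeric reads, clustered with a span-position
    distance metric via maximal-clique enumeration, scored on a 0-100
    scale, and combined into five variant classes: deletions, inversions,
    tandem duplications, interspersed duplications (with genomic origin
    and cut&paste annotation) and novel element insertions. Calls are
    written to five BED files and a VCF. Includes a truth-labelled
    fixture simulator for long-read split alignments and a
    reciprocal-overlap evaluation harness with precision-recall curves.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rsamtools,
    GenomicAlignments,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    VariantAnnotation,
    GenomicRanges,
    jsonlite,
    optparse
Config/testthat/edition: 3
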