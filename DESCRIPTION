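Package: svlr
Title: Somatic Structural Variant Discovery from Tumor/Control Paired
    Long-Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects somatic structural variations (SVs) at single-base
    resolution from coordinate-sorted tumor and matched-control long-read
    alignments. A canonical SV module extracts junction signals from CIGAR
    strings and split alignments, clusters them, subtracts control and
    panel-of-normals evidence, polishes junction-spanning read segments into
    an error-corrected consensus, and refines breakpoints with a
    Smith-Waterman variant that permits a one-time jump between two genomic
    regions. A single-breakend module recovers rearrangements whose partner
    sequence cannot be placed uniquely (satellite, telomere, LINE1-, Alu- and
    virus-mediated events) from long soft-clipped reads, and a classifier
    annotates full-length inserted sequences (solo mobile elements, 5'
    inversions, target site duplications, polyA tails, partnered and orphan
    3' transductions, processed pseudogenes). Centromeric contigs are
    decomposed into alpha-satellite monomers and scored against
    chromosome-specific higher-order repeat structures. A synthetic-data
    generator produces toy genomes, injected SVs and noisy reads with exact
    truth so the whole pipeline is testable without external aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    Rsamtools,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
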