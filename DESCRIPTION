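Package: eccscout
Title: Detection of Extrachromosomal Circular DNA from circSeq Read Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for calling extrachromosomal circular
    DNA (eccDNA) candidates from enriched circular-DNA sequencing (circSeq)
    data. Candidate regions are detected from alignments by integrating three
    read signatures of amplified circles on a linear reference: split reads in
    wrap-around orientation at the circular junction, discordantly mapping
    read pairs, and prominence-filtered coverage peaks on bases-per-million
    normalized depth. Independently, enriched circular sequences are detected
    without a reference by comparative k-mer clustering of circSeq versus
    control reads; cluster contigs are then linked back to candidate regions
    (including across the circular breakpoint via rotated region sequences) to
    report very-high-confidence candidates. A built-in circSeq simulator with
    rolling-circle concatemer templates and oracle alignments makes every
    stage testable without external mappers or data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rcpp,
    S4Vectors,
    data.table,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
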