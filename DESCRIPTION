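Package: centerscan
Title: Degenerate Motif Discovery of Hidden Functional Centers in Plant Proteins
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering hidden functional centers in complex
    multi-domain plant proteins with degenerate amino-acid search motifs.
    Implements a PatMatch-style pattern language (residue classes, literals
    and bounded wildcard spacers) with an exact matcher that enumerates all
    occurrences, a curated registry of catalytic-center motifs (guanylate
    cyclase, adenylate cyclase, H-NOX nitric-oxide sensor, abscisic-acid
    modulatory site) with rational derivation operations, consensus motif
    induction from multiple sequence alignments of annotated functional
    centers, proteome scanning with splice-isoform collapsing and exclusion
    lists, expected-occurrence statistics under an i.i.d. residue
    background, and a synthetic proteome generator with planted motif
    instances for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: SequenceMatching, Proteomics, Annotation
RoxygenNote: 7.3.3
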