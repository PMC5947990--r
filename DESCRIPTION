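Package: knocktag
Title: Design of CRISPR-Cas9 Guides and ssODN Donors for C-Terminal Epitope Knock-In
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs SpCas9 guide RNAs and single-stranded oligodeoxynucleotide
    (ssODN) repair templates for scarless knock-in of short epitope tags (V5,
    3XFLAG, HA, Myc) at the C-terminus of protein-coding genes. Given a genome
    and a transcript annotation, the package extracts a stop-codon-centred
    design window, enumerates N20-NGG protospacers, scores them for on-target
    efficiency (Rule Set 2 featurization with a pluggable linear model) and
    specificity (exhaustive mismatch off-target search with MIT-style
    aggregate scoring), prioritises guides cutting 8-15 bp into the 3'UTR, and
    assembles <= 200-mer donors with symmetric homology arms and PAM-blocking
    silent mutations. Single-target and 96-well batch modes are provided,
    together with a synthetic fixture generator with a planted-feature truth
    table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
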