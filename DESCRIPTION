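Package: hgtscan
Title: Detection and Characterization of Horizontally Transferred Regions
    from Pairwise Whole-Genome Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls candidate horizontally transferred (HGT) regions in a
    focal genome from tables of pairwise alignment blocks against mammal and
    non-mammal species panels, characterizes the called regions (chromosome
    end bias, gene-biotype and chromatin-state composition, windowed
    repeat/GC/histone profiles), and lower-bounds the number of transfer
    events per region via the exact rooted subtree-prune-and-regraft (SPR)
    distance between a neighbor-joining region tree and the species tree.
    Ships a synthetic-data generator that plants HGT signals into simulated
    alignment-block tables and annotation tracks so every pipeline stage is
    testable without genome-browser downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    IRanges,
    S4Vectors,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
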