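Package: sairna
Title: Design and Processing Simulation of Ribozyme-Enhanced saiRNA and shRNA Silencing Constructs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing single-stranded Ago2-processed interfering
    RNA (saiRNA) and classical shRNA hairpins against arbitrary target mRNAs,
    and for simulating their fate inside the cell. Covers hairpin construction
    rules (5' adenine start, target-complementary loop, engineered terminal
    mismatch), HDV-ribozyme expression cassettes with RNA polymerase III or T7
    transcription, ribozyme self-cleavage with 2',3'-cyclic phosphate end
    chemistry, stem-length-dependent Dicer versus Ago2 processing, 3'-overhang
    gated Ago2 loading and Argonaute partitioning. Also provides seed-based
    (positions 2-7) off-target scanning of 3' UTR sets with differential
    expression attribution, a synthetic transcriptome generator with planted
    effects, and a small-RNA-seq read profiler (adaptor clipping, sequential
    read categorization, 5'-anchored miRNA counting, per-million normalization,
    5'/3' end-heterogeneity tables) with a matching synthetic read generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
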