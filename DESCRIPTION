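Package: mitoarch
Title: Comparative Architecture of Mitochondrial Genomes: Gene Orders,
    Breakpoints, Ancestral Arrangements and Truncated tRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of animal mitochondrial genome
    architecture, developed around the mite (Acari) system. Parses and
    validates per-genome annotation tables and computes intergenic gaps,
    overlaps, strand usage and codon summaries; extracts circular signed
    gene orders and measures rearrangement as breakpoint distances against
    a reference arrangement; detects shared derived gene clusters
    (candidate synapomorphies); reconstructs ancestral gene arrangements on
    a user-supplied rooted tree by minimum-change (Fitch) parsimony over
    gene-adjacency characters; and classifies mitochondrial tRNA secondary
    structures (cloverleaf, D-armless, T-armless, armless) with a
    template-constrained folder. A seed-deterministic synthetic-data module
    generates rearrangement scenarios along trees, annotated genomes and
    tRNA sequences with known architecture so that every stage is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
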