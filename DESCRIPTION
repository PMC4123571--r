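Package: macadna
Title: Fuzzy Multiple-Attractor Cellular Automata Classifiers for DNA Regions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A fuzzy cellular-automata engine whose attractor basins act as
    class regions for DNA sequence classification. Cells hold real values in
    [0,1] and evolve under bounded-sum (Lukasiewicz) neighbourhood rules; a
    per-cell rule genome is trained by a clonal-selection algorithm with a
    reservoir-recycling modification so that encoded sequences from different
    functional classes (promoter, exon, intron, 3'UTR) drain to differently
    labelled attractors. Includes promoter-element and coding-measure feature
    encoders (TATA/CAAT/Inr consensus scores, k-mer composition, codon
    position asymmetry, hexamer bias), a hierarchical classification pipeline
    with sliding-window boundary calling, a synthetic labelled-sequence
    generator, FASTA/TSV/BED-style input and output, one-vs-rest evaluation
    metrics, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
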