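Package: cubkit
Title: Codon Usage Bias Analysis for Chloroplast Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying codon usage bias (CUB) in organellar
    protein-coding gene sets. Reads CDS collections from FASTA or GenBank
    flat files and applies a five-rule quality filter; computes positional
    GC composition (GC1/GC2/GC3/GC3s), relative synonymous codon usage
    (RSCU), relative frequency of synonymous codons (RFSC) and
    high-frequency codon screens; diagnoses mutation versus selection
    pressure with the effective number of codons (ENc) against its
    expected GC3s curve, parity-rule-2 (PR2) plots and the neutrality
    (GC12 on GC3) regression; runs correspondence analysis on gene-level
    RSCU matrices; estimates expression-related bias with SCUO and MILC
    and their correlation; and clusters genomes by squared Euclidean
    distance between RSCU profiles with between-groups average linkage.
    A seeded synthetic CDS generator with controlled codon bias, GC3
    gradients and neutrality-slope structure makes every stage testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    ape
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
biocViews: Software, Genetics, Phylogenetics
RoxygenNote: 7.3.3
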