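Package: mitocompare
Title: Comparative Analysis of Annotated Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated insect mitochondrial
    genomes, built around the typical blattarian (cockroach) genome: parsing of
    GenBank flat files and 1-based feature tables, strand-aware gene extraction,
    intergenic spacer and gene-overlap accounting, nucleotide composition and
    AT/GC skew, codon usage and RSCU under the invertebrate mitochondrial code,
    incomplete stop-codon classification, control-region structure analysis
    (IUPAC motif scanning, tandem-repeat detection, conserved-block detection in
    alignments, stem-loop prediction with loop T-stretch annotation), Kimura
    two-parameter distances with analytic standard errors, DNA barcoding-gap
    summaries, codon-position substitution-saturation profiles, neighbor-joining
    trees, and construction of partitioned phylogenetic supermatrices
    (ALL-123, ALL-12, PCG-123, PCG-12). A synthetic-genome generator with a
    ground-truth ledger makes every stage testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
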