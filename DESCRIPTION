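Package: mitocompare
Title: Comparative Analysis of Fungal Mitochondrial Genomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated fungal mitochondrial
    genomes: base composition and strand-skew statistics, region partitioning
    (protein-coding, intronic, intergenic, RNA), codon usage under the mold
    mitochondrial genetic code, detection of interspersed, exact
    (forward/reverse/complement/palindromic) and tandem repeats,
    mitochondrial-to-nuclear transfer fragment detection, classification of
    cox1 group I introns into reference-anchored position classes (Pcls) with
    common/rare prevalence calls, signed circular gene-order extraction and
    breakpoint-distance comparison of the conserved 17-gene set, and
    preparation of concatenated multi-gene supermatrices with partition files
    and a neighbor-joining sanity tree. A synthetic-data generator produces
    annotated mitogenomes, clades and paired nuclear sequences with known
    planted structure so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Genetics, Phylogenetics, ComparativeGenomics, Alignment
RoxygenNote: 7.3.3
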