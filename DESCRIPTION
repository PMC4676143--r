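Package: spfam
Title: Annotation and Comparative Analysis of Serine Protease Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rule-based annotation of insect serine protease (SP) and serine
    protease homolog (SPH) gene families from predicted protein sequences and
    gene models. Detects the His/Asp/Ser catalytic triad through conserved
    sequence motifs, classifies proteins as catalytically active SPs or
    inactive SPHs, locates N-terminal clip domains by their six-cysteine
    spacing grammar, calls trypsin/chymotrypsin substrate specificity from the
    S1 pocket residues (chymotrypsinogen numbering), and types zymogen
    activation sites. Companion analyses cover tandem-duplication clustering
    on genome scaffolds, intron-phase computation, Poisson-corrected
    neighbor-joining phylogenies with bootstrap support, and hierarchical
    clustering of log2 RPKM expression matrices. A synthetic-family generator
    with a ground-truth manifest makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
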