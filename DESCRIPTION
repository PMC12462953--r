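Package: polyphase
Title: Subgenome Partitioning of Allopolyploid Genomes by Differential
    K-Mer Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assigns the chromosomes of an allopolyploid assembly to
    subgenomes by comparing MinHash (Mash) distances between each
    polyploid chromosome and homologous chromosomes of a related diploid
    reference: within each homoeologous pair, the member closer to the
    reference is placed in one subgenome and the more diverged member in
    the other. Includes bottom-s MinHash sketching of canonical k-mers
    with an exact-Jaccard oracle, greedy homoeolog pairing with a
    user-supplied override, ambiguity flagging for near-equal distances,
    a heterozygous k-mer-pair (smudgeplot-style) ploidy module that
    classifies genotype structure (AB, AAB, AABB, ...) from read
    coverage, and a deterministic allotetraploid genome and read
    simulator used as the test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
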