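Package: peqclust
Title: Proteome-Based Phage Genome Similarity and Clustering
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes proteome-anchored pairwise similarity metrics between
    phage genomes described by gene-phamily (pham) membership and protein
    translations: Jaccard coefficient, gene content similarity, percentage of
    conserved proteins, alignment fraction (AF), average amino acid identity
    (AAI), and the proteomic equivalence quotient (PEQ = AF x AAI). Genomes
    are assorted into clusters by a two-iteration greedy threshold
    agglomeration (complete-linkage pre-clustering of highly homogeneous
    groups, then average-linkage clustering of group medoids) and optionally
    subclustered by single linkage. Predicted partitions can be evaluated
    against reference assignments with unordered-pair confusion counts,
    precision, sensitivity, and the Matthews correlation coefficient. A
    synthetic pham-table generator with planted cluster structure supports
    testing and benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
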