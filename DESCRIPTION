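Package: lpam
Title: Overlapping Community Detection by Link Partitioning Around Medoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects a user-specified number of overlapping communities in an
    unweighted undirected graph by clustering the nodes of its line graph
    around medoids. Pairwise dissimilarities between edges are measured with
    the commute (resistance) distance or the amplified commute distance,
    computed from the Moore-Penrose pseudoinverse of the line-graph
    Laplacian. The k-median problem is solved exactly (pruned enumeration
    certifying global optimality) or heuristically (CLARANS randomized local
    search). Edge clusters are mapped back to an overlapping node cover via
    thresholded belonging coefficients. Includes evaluation metrics for
    overlapping covers (overlapping NMI in LFK and max-normalized variants,
    omega index, symmetrized best-match F1), per-cover graph statistics
    (average internal degree, normalized cut), synthetic benchmark
    generators (grid lattice, planted partition, stochastic block model),
    community-file I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
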