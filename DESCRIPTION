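Package: decyclr
Title: Minimum Decycling Sets of k-mers and Sketching Window Guarantees
Version: 0.1.0
Authors@R:
    person("decyclr", "maintainers", email = "decyclr@example.org",
           role = c("aut", "cre"))
Description: Tools for constructing, verifying, enumerating and optimizing
    minimum decycling sets (MDSs) of k-mers, the unavoidable k-mer sets that
    give sequence-sketching methods their window guarantee. Implements the
    F-move/RF-move/I-move calculus on MDSs, layered traversal of the MDS
    graph and its component graph, constrained-cycle discovery of valid
    I-moves, remaining-path-length computation (the window guarantee of the
    associated context-free sketching scheme), the Mykkeltveit minimum
    decycling set, syncmer-like positional-minimum schemes, and a simulated
    annealing search for MDSs with extremal remaining path length.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
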