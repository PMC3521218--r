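Package: hepmotif
Title: Hybrid Exact Planted (l,d) Motif Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact discovery of planted (l,d) DNA motifs by a hybrid
    two-stage strategy: an analytic cost model selects how many input
    sequences to hand to an exhaustive neighborhood search, candidate
    motifs are generated exactly from that subset, and the remaining
    sequences are used only to validate candidates by approximate
    pattern matching. Includes the probability model for the expected
    number of spurious motifs in random sequences, the subset-size
    planner (minimum and optimal number of sequences), a deterministic
    lane-parallel execution mode, a planted-instance simulator with
    ground truth, a brute-force reference search, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    methods,
    optparse,
    parallel,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
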