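Package: netgp
Title: Symbolic Regression of Generative Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers network growth rules by symbolic regression. Growth
    rules ("generators") are expression trees that assign weights to candidate
    arcs; networks are grown arc-by-arc by stochastic selection proportional to
    those weights. Candidate generators are scored against a target network
    with a multi-metric dissimilarity (degree, PageRank, distance and triadic
    profile distributions) normalized by an Erdos-Renyi baseline, and evolved
    by sub-tree mutation under an anti-bloat rule until a concise generator
    reproducing the target's structure is found. Includes tools to grow
    networks from generator programs, compare networks, and quantify the
    behavioural dissimilarity between two generators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    stats
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
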