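Package: annealMP
Title: Simulated Annealing Search for Maximum-Parsimony Phylogenies with
    Phase-Transition Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instrumented simulated annealing over unrooted binary tree
    topologies under the maximum-parsimony criterion, with the homoplasy
    index as cost function. Provides PHYLIP alignment input/output, Fitch
    tree-length scoring with site-pattern compression, nearest-neighbour
    interchange and subtree pruning-regrafting proposals, linear and
    geometric cooling schedules with freezing, per-temperature cost
    sampling, specific-heat profiles with critical-temperature (peak)
    detection, temperature-stratified strict consensus trees for
    convergence analysis, a sequence evolution simulator with controlled
    homoplasy, and replicated experiment designs (Boltzmann-constant
    scaling, initial-temperature benchmarking).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
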