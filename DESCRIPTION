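Package: exitentry
Title: Exit-Entry Dynamics of Two Interacting Cell Populations on Regular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the competition between two cell populations (e.g. the
    classically and alternatively activated macrophage phenotypes that remodel
    the left ventricle after myocardial infarction) as an exit-entry
    (death-birth) process on a k-regular interaction network. Provides a fast
    stochastic agent-based simulator, the pair-approximation reduction of the
    dynamics under weak selection, and an analytic stability classifier that
    predicts from the 2x2 interaction matrix, the vertex degree and the
    initial frequency whether one population dominates, vanishes, or the two
    coexist at an interior equilibrium.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
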