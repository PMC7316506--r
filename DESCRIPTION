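Package: hgtgenes
Title: Horizontal Gene Transfer of Slightly Beneficial Genes and Selfish Elements
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models of bacterial populations taking up DNA from a shared gene
    pool. Implements the well-mixed chemostat theory of costly gene uptake
    (closed-form steady states, the population growth rate as a function of
    the uptake rate, the optimal uptake rate, and the five-way classification
    of genes into indispensable, enrichable, rescuable, unrescuable and
    selfish), an adaptive-dynamics invasion analysis of uptake-positive
    versus uptake-negative strains (invasion fitness, evolutionary stability,
    founder-size basins of attraction), and a stochastic individual-based
    model on a toroidal lattice in which the uptake rate evolves de novo and
    host cells coexist with selfish genetic elements. Includes a measurement
    layer (population and line-of-descent growth rates, local competitive
    advantage of carriers, gene barcoding) and protocol drivers that
    reproduce the analysis end to end.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
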