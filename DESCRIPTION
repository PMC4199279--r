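Package: mspnet
Title: Homeostatic Structural Plasticity in Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates spiking neuronal networks in which neurons grow and
    retract axonal and dendritic synaptic elements to homeostatically restore
    their firing rate (a model of structural plasticity). Networks of
    Izhikevich neurons are grown from scratch, a focal loss of external input
    (lesion projection zone) is applied, and the ensuing rewiring is tracked
    with weighted directed graph-topology measures: characteristic path
    length, Fagiolo clustering, small-worldness against an Erdos-Renyi null,
    Brandes betweenness centrality, and local/global efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    yaml,
    jsonlite,
    stats,
    graphics,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
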