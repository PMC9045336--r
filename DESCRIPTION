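Package: miconet
Title: Co-Occurrence Networks, Keystone Taxa and Stability of Microbial
    Communities
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds signed co-occurrence networks from OTU count tables
    (Spearman correlation on log-transformed relative abundances with a
    random-matrix-theory similarity threshold), characterizes their
    topology and modular structure against degree-preserving randomized
    nulls, classifies nodes into network hubs, module hubs, connectors
    and peripherals from within-module (Zi) and among-module (Pi)
    connectivity, and quantifies community stability through positive
    and negative cohesion, the N:P ratio, node-removal vulnerability and
    the negative-link ratio. Includes a synthetic rarefied-count
    generator with planted modules, roles and a developmental stage
    schedule so that the whole pipeline is testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    biomformat,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
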