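Package: crowdsim
Title: Agent-Based Simulators of Mass Behavior
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Seeded, reproducible simulators for three stylized mass
    behaviors: a visibility-scaled threshold cascade of panic buying with
    an analytic fixed-point oracle, an asynchronous social-learning model
    of behavioral conformity on Watts-Strogatz small-world networks, and a
    modified SIR contagion of conspiracy belief with assortative believer
    matching, belief reinforcement, and cumulative counter-influence.
    Includes sweep runners, scenario presets with replicate orchestration
    and run manifests, and plain-text edge-list network input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
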