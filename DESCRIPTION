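Package: microbehave
Title: Host-Microbiome Behavioral Feedback Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates coupled host-microbiome dynamics in which microbial
    strains compete for host-behavior-dependent resources while feeding
    back on the host's behavior through reward and aversion signals or a
    direct behavioral pull. Implements discrete-time logistic competition
    with relative-abundance normalization and a generalized Lotka-Volterra
    variant, sliding-window trend feedback, three-phase
    addiction-withdrawal-relapse scenarios with richness interventions,
    phase metrics, seeded ensembles, parameter sweeps and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
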