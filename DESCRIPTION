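Package: sarcoreg
Title: Cooperative Thin-Filament Regulation and Contractility Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A stochastic Markov-chain model of cooperative thin-filament
    regulation with isoform-specific modulation by myosin binding protein-C
    (MyBP-C), together with the analysis pipelines used in steady-state and
    dynamic contractility experiments: force-pCa Hill fitting, rate of
    tension redevelopment (k_tr), NADH-coupled ATPase rates and tension
    cost, in vitro motility statistics (velocity x fraction moving), and
    unloaded sarcomere-shortening twitch kinetics. Includes an EGTA
    solution-chemistry calculator for free calcium and pCa, and seeded
    synthetic-data generators with declared ground truth so every pipeline
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
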