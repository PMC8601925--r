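Package: hitchsweep
Title: Two-Locus Genetic Hitchhiking with Recurrent Beneficial Mutation and Purifying Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deterministic and semi-deterministic analysis of selective sweeps in a
    two-locus, two-allele model with additive fitness, continuous mutational pressure
    at the selected locus and (optionally) purifying selection at the linked locus.
    Provides the gamete-frequency and transformed-coordinate ODE systems, closed-form
    sweep solutions for the tractable parameter regimes (including the soft-sweep
    threshold kappa = mu_B/s2 and the post-sweep heterozygosity ratio under
    mutation-selection balance), diffusion-approximation moments for the stochastic
    initial phase of the beneficial allele, a discrete-generation two-locus
    Wright-Fisher forward simulator used as a brute-force oracle, soft-sweep
    classification and scanning, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
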