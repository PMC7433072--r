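Package: aesignal
Title: Two-Stage Bayesian Safety Signal Detection for Clinical Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Interim safety monitoring of adverse events in randomized
    clinical trials using a two-stage Bayesian procedure. Stage 1 screens
    blinded (pooled) adverse-event counts for potential safety signals with
    either an independent Beta-Binomial model or a Bayesian hierarchical
    blinded model that shrinks per-event log-odds offsets toward a shared
    mean. Stage 2 confirms flagged signals on unblinded per-arm counts with
    a Bayesian hierarchical logistic dose-response model. Includes a seeded
    adaptive random-walk Metropolis-within-Gibbs sampler, an interim
    monitoring workflow that enforces the blinding contract, and a scenario
    simulator for operating characteristics (per-event flag and confirmation
    proportions, family-wise error rates) of the eight-arm hyperbaric-oxygen
    trial design that motivates the package.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    coda,
    optparse,
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
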