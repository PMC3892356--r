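Package: atlasdyn
Title: Three-Level Dynamic Occupancy Models for Gridded Atlas Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a hierarchical Bayesian dynamic occupancy model to
    detection/nondetection checklist data collected on a regular grid over
    two atlas periods. The model has three levels: season-scale occupancy
    with penalized-spline habitat smooths, an intrinsic conditional
    autoregressive (CAR) spatial random field and autologistic
    persistence/colonization dynamics between periods; yearly use dynamics
    within each period (relaxing the closure assumption); and two
    protocol-specific observation models, one per-checklist and one built
    from hourly detection during an initial period of intense birding.
    Inference is by Metropolis-within-Gibbs MCMC with exact Bernoulli data
    augmentation for the latent occupancy and use states, implemented in
    compiled code. A synthetic atlas-data simulator drawing from the exact
    generative model makes the full inference chain testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
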