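Package: wienerhdm
Title: Hierarchical Wiener Diffusion Modelling of Two-Choice Priming Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing two-choice response-time experiments with a
    hierarchical Bayesian Wiener diffusion model, motivated by affective
    priming tasks under continuous flash suppression. Provides the Wiener
    first-passage-time density (small-time and large-time series with an
    error-bounded switching rule), analytic choice probabilities and moments,
    a first-passage simulator, a synthetic-dataset generator with known
    ground truth, the standard response-time exclusion cascade with a full
    audit report, an adaptive Metropolis-within-Gibbs sampler for the
    hierarchical model (condition-level drift and nondecision means,
    participant-level boundary separation, trial-level variability
    marginalised out), convergence diagnostics (split R-hat), highest-density
    intervals, posterior condition contrasts, and posterior-predictive
    response-time quantile checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
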