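Package: loudsim
Title: Simulated Categorical Loudness Scaling and Neural-Ensemble-Averaging Loudness Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying mid-bandwidth loudness depression with simulated
    listeners. Synthesizes narrow-band test stimuli (pure tones, Rayleigh-spectrum
    band noise, five-tone complexes, low-noise noise, SAM tones), generates
    synthetic normal-hearing and hearing-impaired cohorts with parametric
    categorical-loudness surfaces, runs a Bayesian adaptive categorical
    loudness-scaling procedure over frequency and level, fits loudness profiles
    (category-boundary levels across frequency), and derives loudness growth
    slopes, loudness reduction and summation, equal-loudness contours, and
    mixed-model group statistics. Includes a neural-ensemble-averaging loudness
    model: a compressive gammatone periphery, three-store diffusion synaptic
    adaptation, Poisson fiber rates, and ensemble averaging sandwiched between
    spike-rate compression and perceptual expansion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Rcpp,
    lme4,
    lmerTest,
    emmeans
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
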