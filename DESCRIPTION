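Package: platekd
Title: Plate-Based Dynamic Light Scattering Analysis of the Diffusion
    Interaction Parameter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-throughput protein formulation screening with
    384-well plate dynamic light scattering (DLS). Provides plate geometry
    and layout handling with edge/centre classification and acquisition
    scheduling, a forward simulator of plate-reader DLS runs (concentration
    dependent diffusion D = D0*(1 + kD*c), position- and time-dependent
    evaporation, autocorrelation-function noise, second particle
    populations), autocorrelation analysis by second-order cumulant fits
    and non-negative Tikhonov-regularised size distributions, Grubbs
    outlier-screened estimation of the diffusion interaction parameter kD,
    intra- and inter-plate variability statistics (pooled coefficients of
    variation, one-way and repeated-measures ANOVA, post-hoc t tests, span
    metrics), and generators for API-efficient screening plate designs with
    exact material budgets and Monte-Carlo design evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
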