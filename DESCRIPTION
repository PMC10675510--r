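Package: transflux
Title: Transwell Barrier Transport Analysis with Sampling-Artifact Correction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of transwell barrier transport assays with
    automated basolateral sampling. Corrects adsorption, desorption and
    droplet carry-over artifacts of the sample-collection process with
    discrete recurrence models (single-compartment and basal/lateral
    sub-compartment variants), deconvolves per-interval transmembrane fluxes
    from sampled amounts, estimates diffusive permeability and metabolic loss
    by flux-versus-concentration-difference regression, and fits a
    one-dimensional diffusion-partition-metabolism model of the cell layer by
    explicit finite differences. Includes VIS absorbance calibration
    (baseline correction, medium referencing, piecewise linear/power-law
    concentration maps) and seeded synthetic-data generators for every
    experiment design the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
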