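Package: oxcycle
Title: Oxygen Transport Modelling for Intermittent Hypoxia in 3D Culture
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the delivery of fast intermittent hypoxia (obstructive
    sleep apnea-like oxygen cycling, up to 60 events/h) through a
    gas-permeable membrane into three-dimensional culture scaffolds such as
    extracellular-matrix hydrogels and precision-cut tissue slices. Provides
    a one-dimensional multilayer reaction-diffusion solver with
    Michaelis-Menten cellular oxygen consumption, closed-form diffusion-time
    and consumed-versus-diffused flux estimates, depth-resolved
    periodic-steady-state envelope analysis, a synthetic oxygen-microsensor
    emulator (first-order lag plus Gaussian noise), and least-squares
    recovery of effective diffusivity from depth-tagged sensor traces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
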