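Package: myoratchet
Title: Flashing Brownian-Ratchet Simulation of the Actomyosin Cross-Bridge Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates muscle force generation as a flashing Brownian ratchet:
    myosin heads diffuse in a piecewise-linear multistable actomyosin
    potential under overdamped Langevin dynamics and switch between attached
    and detached states through a strain-dependent jump process. Provides the
    single-molecule micro-needle experiment used to calibrate the potential
    bias from forward/backward jump ratios, half-sarcomere ensemble protocols
    (isometric contraction, length clamp, force clamp), first-passage-time
    machinery for barrier calibration, and analysis of tension transients
    (T1/T2), force-velocity curves, attachment and strain statistics, and
    thermodynamic efficiency with its flashing-ratchet upper bound.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
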