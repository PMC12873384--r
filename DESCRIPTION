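Package: silkgel
Title: Multimodal Analysis of Silk-Fibroin Gelation from Time-Resolved
    Small-Angle Scattering and Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the sol-gel transition of reconstituted silk
    fibroin monitored simultaneously by time-resolved small-angle neutron
    scattering (SANS), thioflavin-T fluorescence, turbidity, pH and FTIR.
    Implements a two-stage hierarchical composite scattering model
    (power law + Lorentzian, extended with an exponential cut-off and a
    Gaussian correlation peak), model-free scattering metrics (apparent
    invariant, correlation-peak detection), DBSCAN phase mapping of the fitted
    parameter space with convex-hull phase volumes, joint SANS + fluorescence
    multivariate curve resolution by alternating least squares (MCR-ALS),
    sigmoidal thioflavin-T kinetics with onset/midpoint/plateau landmarks, and
    amide-I band kinetics. A seeded synthetic-data generator emulates the
    full multimodal experiment so every stage is testable without beamline
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
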