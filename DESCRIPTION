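Package: dosim
Title: Mechanobiological Simulation of Distraction Osteogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An axisymmetric viscoelastic finite-element model of a distracted
    bone regenerate coupled to a fuzzy-logic mechano-regulatory tissue
    differentiation controller. Simulates latency, constant-rate and
    rate-varying distraction, and consolidation phases of distraction
    osteogenesis; predicts interfragmentary movement, regenerated bone area,
    tissue concentration maps, and time to bony bridging. Includes Prony-series
    fitting of stress-relaxation curves, a protocol grammar for rate-varying
    distraction schedules, and an effective-strain design rule for protocol
    design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
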