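Package: patchcomm
Title: Patch-Occupancy Community Dynamics Under a Competition-Fecundity
    Trade-Off
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying plant community structure with a Levins-type
    colonization (patch-occupancy) model in which hierarchical displacement
    competition is paid for by reduced fecundity. Provides the saturating
    competition-fecundity trade-off, a forward-recursive equilibrium solver,
    continuous-time dynamics with scheduled fertilization events and weak
    immigration, rank abundance diagrams with detection thresholds and
    labeled-SAD comparisons (new, lost, retained and reordered species), and
    experiment drivers for fertilization scenarios, alpha-beta response
    surfaces, factor decompositions and trade-off fluctuation robustness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
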