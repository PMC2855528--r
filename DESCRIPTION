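Package: hfpne
Title: Hybrid Functional Petri Net Simulation and Active State Transition
    Diagram Mining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates hybrid functional Petri nets with extension (HFPNe),
    a Petri-net formalism with discrete, continuous and generic places and
    transitions used to model biological pathways.  Provides fixed-step
    execution producing time-course traces (EDF), extraction of the minimal
    active subnet at every sampled time point, construction of the active
    state transition diagram (ASTD) that deduplicates those subnets into a
    directed multigraph of structural states, and graph analytics on the
    result (state durations, out-degree on a natural-log scale, per-place
    total concentration differences, two-model comparison, DOT/GraphML
    export).  Ships a toy oscillator, a seeded random-net generator and a
    parameter-configurable circadian-clock scaffold so every stage is
    testable without external model files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
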