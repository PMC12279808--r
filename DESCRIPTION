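Package: gmacorn
Title: Lightweight Corn Whorl Detection, Spray Decision Logic and Delivery
    Timing Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building precision granular-pesticide application
    pipelines for row-planted corn at the V6-V8 stage. Provides closed-form
    implementations of three lightweight feature operators (GhostConv,
    SimAM and mixed local channel attention), a configurable anchor-free
    single-class detector family (a YOLOv8n-style baseline and a
    Ghost-HGNetV2 variant with attention-augmented neck and an auxiliary
    training head) with exact parameter and FLOP profiling, task-aligned
    and SimOTA label assignment with a smoke-scale training loop, the
    spray-decision engine that turns per-frame detections into actuation
    packets, a front-camera/rear-funnel delivery timing simulator, the
    standard detection and field-trial delivery metrics, and a procedural
    generator of annotated overhead corn-canopy scenes for end-to-end
    testing without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
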