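Package: flowspot
Title: Diffractive Flat-Top Illumination Spots and Signal Simulation for
    Micro Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Design toolkit for micro-flow-cytometer illumination based on
    multi-level diffractive phase elements. Implements iterative
    Fourier-transform (Gerchberg-Saxton) design of quantized phase masks
    that place rectangular quasi-flat-top spots in a lens focal plane,
    quantitative spot evaluation (diffraction efficiency, RMS amplitude and
    intensity uniformity, half-maximum dimension measurement), a laminar
    flow-resistance model of a 3D hydrodynamic-focusing chip including the
    rectangular-duct velocity profile, a photomultiplier waveform simulator
    for fluorescent beads transiting single- or multi-rectangle spots, and
    pulse analysis with 90-percent-gated CV statistics and dual-spot
    time-of-flight velocimetry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
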