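Package: veinscan
Title: Simulation and Demultiplexing for Multi-Wavelength NIR Finger-Vein
    Acquisition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Software pipeline of a multi-wavelength near-infrared (NIR)
    finger-vasculature acquisition device. Provides a procedural finger
    optical phantom (Beer-Lambert trans-illumination at 730/875/940 nm plus
    a front-lit skin-texture mode), a free-run rolling-shutter camera
    simulator driven by a 13-pattern illumination protocol with in-frame
    7-segment state indication, the post-processing algorithm that
    demultiplexes the unsynchronized video into one clean image per
    illumination window (detector pixels, dark-frame delimiters, per-pixel
    maximum, background subtraction), and extraction of the blood-pulse
    waveform from the demultiplexed series for liveness assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    yaml,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
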