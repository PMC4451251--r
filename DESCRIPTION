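Package: keyfusion
Title: Fusing Camera Marker Tracking, Key-Surface Touch Sensing and MIDI for
    Keyboard Performance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrating three independently clocked sensor streams
    recorded from a piano keyboard: overhead-camera tracking of painted hand
    markers, capacitive key-surface touch frames, and MIDI key events.
    Provides drift-corrected temporal alignment onto a camera-anchored
    timeline, spatial registration of markers and touches through per-key
    polygons, keyboard detection from a hands-free image, automatic two-pass
    fingering annotation, and three kinematic analyses: finger curvature
    index, touch-versus-MIDI anticipatory and release timing, and
    transition-window quantity-of-motion with lift/fall/slide
    classification. Includes a deterministic synthetic-performance simulator
    with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    EBImage,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
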