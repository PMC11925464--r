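Package: valveflow
Title: Quantitative Image Analysis of Drosophila Intracardiac Valve Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for video-based assays of cardiac performance
    in Drosophila larvae and prepupae with malformed intracardiac valves.
    Implements dye-angiography accumulation indices, peri-valve intensity
    oscillograms with pump-cycle and cardiac-arrest detection, two-ROI
    transit-time velocimetry, dye-packet flood-fill segmentation, valve
    luminal gap kinematics, particle spot detection and track linking with
    valve-region speed gating, Fourier-based myofiber directionality,
    moment-based shape descriptors (roundness), crawling-track metrics, and
    the group statistics used with these assays. A synthetic-scene generator
    produces ground-truth videos (pulsatile packet transport, periodic valve
    occlusion, continuity-driven particle advection, oriented fiber textures,
    crawling silhouettes) so that every estimator can be validated by
    parameter recovery without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
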