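Package: spindlequant
Title: Quantification of Mitotic Spindle Architecture from Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying mitotic spindle architecture in multi-channel
    3D and 4D fluorescence microscopy: ratiometric estimation of microtubule
    numbers in kinetochore, bridging and astral fibers from tubulin intensities;
    3D interkinetochore geometry with axial refractive-index correction;
    re-slicing of side-view z-stacks into an end-on view with automated bundle
    counting; circle-fit curvature and contour length of microtubule bundles;
    poleward-flux and anaphase A/B kinetics from photoactivation marks and
    trajectories; classification of chromosome segregation errors; and PRC1
    antiparallel-overlap metrics. Includes a synthetic spindle generator that
    renders ground-truth spindle models into calibrated noisy image stacks and
    time-lapses, so every measurement stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    withr,
    yaml,
    tiff,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
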