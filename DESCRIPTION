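Package: mrgridqa
Title: Geometric Distortion Quality Assurance for MRI and MR-Linac with a
    Grid Phantom
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying MRI geometric distortion with a
    water-filled 3D-printed grid phantom, aimed at quality assurance of
    MR-guided radiotherapy systems. Provides a parametric model of the
    phantom and its control-point lattice, a synthetic scan simulator that
    renders CT-role reference and MR-role distorted volumes under a
    parametric gradient-nonlinearity plus B0 off-resonance displacement
    field, sub-pixel automatic detection of grid intersections, plane and
    3D distortion statistics with radial summaries and threshold
    fractions, and a simplified geometric dose-impact analysis on a
    synthetic dose grid. A pipeline driver ties the stages together and
    emits reproducible CSV/JSON report bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    grDevices,
    graphics,
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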