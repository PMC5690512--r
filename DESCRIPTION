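Package: autoplanr
Title: Autopiloted DVH-Guided Radiotherapy Plan Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated inverse treatment planning on synthetic phantoms: an
    outer-loop autopilot that repeatedly re-parameterizes a surrogate
    fluence-map optimizer until the plan's dose-volume histogram (DVH)
    matches a reference plan's DVH segment-by-segment within tolerance.
    Includes knowledge-based reference-plan selection by signed radial
    contour differences, structure-set Boolean geometry, cumulative DVH
    computation with Vx/Dx statistics, a documented per-structure DVH file
    dialect, and a 2D phantom generator with a pencil-beam dose-influence
    model so the whole pipeline runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mgcv,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
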