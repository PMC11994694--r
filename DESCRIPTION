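Package: seedyield
Title: Seed-Count-Based Yield Estimation for Soybean Breeding Plots from
    Ground-Robot Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale, fully synthetic re-implementation of a
    ground-robot video pipeline for soybean plot yield estimation: fisheye
    distortion and correction, plot-interval frame assignment and
    splitter-based frame sampling, camera-sensor-effect data augmentation,
    a point-proposal seed counting network with Hungarian matching loss
    and duplicate merging, a frozen-backbone yield regression head,
    moving-grid spatial adjustment of plot phenotypes, and
    selection-threshold genotype ranking metrics.  A synthetic field and
    scene generator supplies every input the real pipeline would obtain
    from the field, so the whole chain is testable without any imagery
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
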