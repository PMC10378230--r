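Package: neutraltrack
Title: Three-Dimensional Neutral-Track Cephalometric Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Enlow-style individual and neutral tracks from named
    craniofacial landmark coordinates, in both the classical
    lateral-cephalogram (2D) form and a CBCT-derived 3D form. Constructs
    the subject's middle cranial floor, pterygo-mandibular, mandibular
    ramus and functional occlusal planes, executes the full neutral-track
    geometric construction (Ba-centred sphere, 40.3 degree cranial-base
    angle, parallel and perpendicular plane rules), measures the
    diagnostic angles, and reproduces the paired 2D-versus-3D agreement
    procedure on synthetic cohorts. Landmark I/O covers CSV, JSON and 3D
    Slicer markups FCSV; track planes export to PLY or STL meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
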