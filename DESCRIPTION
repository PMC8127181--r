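Package: energyscape
Title: Energy Landscapes of Diving Seabirds from Biologging Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds foraging energy landscapes for central-place diving
    seabirds (penguins) from raw biologging traces. Computes Overall
    Dynamic Body Acceleration (ODBA) from tri-axial accelerometry,
    segments time-depth-recorder traces into dives with bottom phases,
    classifies dives benthic or pelagic by the intra-depth-zone rule,
    georeferences dives along GPS tracks, calibrates depth-dependent
    regressions of dive cost and bottom time, and projects the
    mass-specific total cost of foraging per unit bottom time (TRC) onto
    a bathymetric grid with inverse-distance-weighted interpolation. A
    seeded synthetic-deployment generator with known ground truth makes
    every stage testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    geosphere,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'calibration.R'
    'dives.R'
    'energetics.R'
    'geodesy.R'
    'io.R'
    'landscape.R'
    'odba.R'
    'pipeline.R'
    'synthetic.R'
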