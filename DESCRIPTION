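Package: finwake
Title: Undulatory Swimming Kinematics and Desk-Scale Hydrodynamics of
    Solitary and Paired Fish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits the subcarangiform body-wave model (a double-exponential
    amplitude envelope carried by a traveling wave) to tracked midline
    landmarks of a station-holding fish, generates synthetic digitized
    tracks for validation, builds a deforming NACA-section fish body, and
    computes unsteady hydrodynamic forces on solitary and parallel swimmers
    with a two-dimensional discrete-vortex panel method with free shed
    wake and an empirical flat-plate friction correction.  Reports
    thrust/drag balance, Froude propulsive efficiency, and wake-transect
    flow speeds as functions of pair separation and tail-beat phase.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    pracma,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse
Config/testthat/edition: 3
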