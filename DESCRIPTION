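Package: windloft
Title: Vertical Wind Transport of Biologically Sized Particles in the
    Upper Atmosphere
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: One-dimensional transport model for nanometre- to
    micrometre-sized disc particles lofted by extreme vertical winds in
    the upper mesosphere and thermosphere. Provides threshold, steady-state
    and closed-form transient velocities for a disc in a directed vertical
    flow with unit drag coefficient, an embedded US Standard Atmosphere
    1976 profile (density, temperature, mean free path, 0-200 km) with
    Knudsen-number diagnostics, trajectory integration through the
    density column in quasi-steady or full-ODE mode, ceiling-altitude
    estimation, a seeded generator of oscillatory vertical-wind time
    series, and a scenario runner with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
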