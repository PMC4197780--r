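Package: swellburst
Title: Swell-Burst Cycle Dynamics of Giant Vesicles Under Osmotic Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanistic simulation and analysis of osmotically driven
    swell-burst cycles in giant unilamellar vesicles. Couples van't Hoff
    osmotic pressure, membrane tension from undulation smoothing and area
    stretching, threshold-triggered transient poration, diffusive and
    convective solute effusion through the open pore, and a
    tension-coupled membrane phase-state indicator. Provides an
    event-driven ODE engine with root-located pore opening and closure,
    per-cycle summaries (periods, peak tension, pore lifetime, solute
    loss), a synthetic fluorescence-homogeneity trace generator, and
    analysis tools that recover cycle periods, damping, and effusion
    times from such traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
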