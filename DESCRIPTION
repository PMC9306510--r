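Package: psckit
Title: Simulation and Analysis of Spontaneous and Miniature Postsynaptic Currents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of spontaneous and miniature postsynaptic
    currents (PSCs) recorded in whole-cell voltage clamp. Provides a synthetic
    recording generator (Poisson event trains convolved with biexponential
    kernels plus band-limited noise), template-correlation event detection,
    per-event kinetic measurement (amplitude, 20-80% rise time, halfwidth) with
    artifact filtering, a ratio-derivative algorithm that selects the rise-time
    cutoff separating fast (perisomatic) from slow (dendritic) events,
    event-count-equalized two-group statistics (Kolmogorov-Smirnov,
    Mann-Whitney, Fisher's exact test), and relative-optical-density
    quantification of immunofluorescence grey values with hierarchical
    averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
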