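Package: cuttleflow
Title: Interfacial Dynamics of Liquid-Gas Fronts in Cuttlebone-Inspired Dual Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the motion of liquid-gas interfaces in
    paired millimetric channels inspired by the wavy pillar structure of the
    cuttlebone. Provides the dimensionless numbers and pressure budget that
    govern confined interface motion, integration of the capillary-rise
    momentum equation with its linear and Washburn (square-root-of-time)
    regimes, the front-separation Lyapunov-exponent statistic computed by a
    sliding-window Savitzky-Golay log-slope, a seeded stochastic Darcy-law
    simulator of dual wavy-wall channels, a synthetic top-view frame
    renderer, and a sub-pixel front tracker that closes the loop from image
    stacks back to displacement traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    ggplot2,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
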