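Package: coopsignal
Title: Evolution of Cooperative Signalling in Turbulent Foraging Environments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based and analytical models of costly recruitment
    signalling among foragers tracking a dynamic resource. Provides a
    kinematic synthetic-turbulence generator (divergence-free Fourier
    modes with a prescribed Karman-Obukhov energy spectrum), a scalar
    advection-decay nutrient field on the unit torus, stochastic
    signaller/non-signaller foraging agents, generational evolutionary
    dynamics under roulette-wheel selection, a reduced moving-patch
    model, and an absorbing Markov-chain approximation that predicts
    the relative uptake of signallers and the evolutionarily stable
    number of cooperators from the spatial and temporal correlation
    scales of the resource.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse,
    knitr
Config/testthat/edition: 3
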