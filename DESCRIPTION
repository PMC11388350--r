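Package: rekusync
Title: Nonreciprocal Coupling and Winner-Takes-It-All Synchronization of
    Oscillator Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for studying how embryonic
    segmentation-clock cell ensembles synchronize. Implements classical and
    rectified ("winner-takes-it-all") Kuramoto coupling families, the
    cycle-averaging convolution that turns signal/response interaction
    functions into an effective coupling function, fixed-step integrators for
    coupled pairs (averaged, pulsed, delayed) and mean-field ensembles, a
    synthetic generator of randomization-assay triplet cohorts with
    reporter-like intensity traces, wavelet-ridge and analytic-signal phase
    estimation with circular synchrony statistics, and the ahead/behind
    outcome classification that separates winner-takes-it-all from
    phase-averaging synchronization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
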