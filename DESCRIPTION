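Package: loopclock
Title: Interlocked Feedback Loop Models of Circadian Period Determination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delay differential equation models of the mammalian circadian
    oscillator built from a negative primary feedback loop (PER/CRY repression
    of CLOCK/BMAL1-driven transcription) interlocked with the positive
    REV-ERBa/Cry1 auxiliary loop acting through the RORE element. Provides a
    deterministic method-of-steps integrator with dense output, oscillation
    metrics (period, amplitude, phases, the transcriptional delay created by
    the auxiliary loop), in-silico amplitude-plane sweeps relating the
    PLBS/RORE intensity ratio to period length, loop-coupling (transmission)
    analyses, a virtual genotype panel, and an experimental-data pipeline for
    replicate qPCR time courses and bioluminescence traces, together with
    seeded synthetic-data generators for testing every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    zoo,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
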