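Package: cftnoise
Title: Chemical Fluctuation Theorem Toolkit for Gene-Expression Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic and simulation machinery for the chemical fluctuation
    theorem relating transcription-rate fluctuations and mRNA lifetime
    statistics to mRNA copy-number variability. Provides phase-type mRNA
    lifetime models, time-correlation functions (TCFs) of transcription-rate
    factors including renewal-process rate TCFs, the steady-state noise
    decomposition with susceptibilities, extensions to gene copy-number
    variation and RNA-polymerase sharing, a generalized mixture law for
    cell-to-cell heterogeneity, an event-driven non-Markovian stochastic
    simulator used as a brute-force oracle, and least-squares fitting of
    telegraph-type transcription models to noise-versus-mean curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
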