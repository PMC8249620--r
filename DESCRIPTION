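Package: sigburst
Title: Signal-Activated Bursting Gene Expression Models via Finite State Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models single-cell mRNA copy-number distributions of LPS-induced
    cytokine genes (IL-1 beta, TNF-alpha) with signal-activated two- and
    three-state stochastic bursting models driven by a shared time-varying
    NF-kB nuclear signal. Solves the time-inhomogeneous chemical master
    equation by Finite State Projection with a truncation-error certificate,
    simulates exact single-cell trajectories for synthetic smFISH-style count
    tables, fits models across inhibitor conditions by a cell-weighted
    Kullback-Leibler (multinomial likelihood) objective, screens candidate
    mechanisms by BIC, and predicts the combined-inhibitor condition from
    single-drug fits without refitting.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    expm,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
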