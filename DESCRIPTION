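Package: hesidyn
Title: Delayed Hes-ID-Proneural Circuit Dynamics and Neural Stem Cell Fate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the Notch-driven Hes auto-repression oscillator with
    transcription-factor dimerization and ID-protein sequestration as a delay
    differential equation system, classifies neural stem cell fate (quiescent,
    active, differentiating) from proneural activity, builds dose-response
    curves and two-parameter phase diagrams, and validates the circuit's
    predictions on single-cell RNA-seq style expression matrices via
    marker-panel scoring, subpopulation classification and PCA. Includes a
    synthetic expression-matrix generator emulating adult subventricular-zone
    and embryonic ventricular-zone progenitor populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma,
    Matrix,
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
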