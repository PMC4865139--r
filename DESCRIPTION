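Package: dgenhancer
Title: Mapping Gibbs-Energy-Sensitive Translation-Regulatory Elements in
    5'UTRs and Designing Translation-Enhancing Oligonucleotides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scans 5' untranslated regions by in-silico saturation
    single-nucleotide substitution to locate positions where mutations
    perturb the folding Gibbs energy the most, smooths the per-position
    perturbation into a windowed signal, and calls candidate cis-acting
    translation-regulatory elements at signal maxima.  Ships two built-in
    minimum-free-energy folding engines (a weighted base-pair-maximisation
    model and a simplified nearest-neighbor thermodynamic model) verified
    against an exhaustive structure-enumeration oracle, plus an adapter for
    an external ViennaRNA-compatible folding engine.  Fits the exponential
    relation between 5'UTR folding energy and relative translation
    efficiency by log-linear least squares, computes translational
    regulatory potential, and designs sense, antisense, microRNA-like and
    scrambled-control oligonucleotides (dGoligos) against called elements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
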