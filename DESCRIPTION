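Package: ligbias
Title: Ligation-Bias Analysis for Small RNA Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and simulating RNA-ligase sequence and
    secondary-structure bias in small RNA next-generation sequencing
    libraries. Implements Poisson count-distribution modelling of degenerate
    (fully randomised) oligonucleotide libraries with a chi-squared
    goodness-of-fit test, minimum-free-energy secondary structure prediction
    (a built-in stacking-weighted dynamic program plus an RNAfold bridge),
    per-position base-pairing profiles anchored at adapter ligation
    junctions, high-definition (degenerate-tag) adapter combinatorics and
    barcode-capture diagnostics, miRNA quantification with reads-per-million
    normalisation, detection-threshold curves, fold-change concordance,
    arm-switch detection and candidate filtering, platform-bias comparison
    of MFE distributions, and a seeded synthetic library simulator with a
    structure-dependent two-step ligation bias model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
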