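Package: cicdr
Title: Reverse Engineering of Immune Biomarker Interaction Networks from
    Serial Blood Draws
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a systems-analysis pipeline for serial peripheral-blood
    immune biomarker panels (cytokines and cell phenotypes). A declarative
    Knowledge Model enumerates all biologically admissible
    modulator/source/target relationships; per-instant characterization
    matrices built from a truncated Kolmogorov-Gabor polynomial over
    generalized Lotka-Volterra dynamics are factored by a Golub-Kahan-Reinsch
    singular value decomposition with configurable early-stopping policies;
    the underdetermined inverse problem is solved by the minimum-norm
    pseudo-inverse; singular-vector activity is converted into normalized
    occurrence counts aggregated into quad, triplet, doublet and singlet
    views, with cohort averaging, differencing and flow-diagram export.
    Includes a seeded synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
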