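Package: viroplan
Title: Experimental Design and Read Simulation for Viral Metagenomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and simulating viral metagenomics sequencing
    experiments. Implements exact evaluation of the abundance-generalised
    Stevens circle-covering probabilities (gap-count and full-coverage
    probability for a target genome of given relative abundance) using
    arbitrary-precision arithmetic, an iterative sequencing-run planner that
    accumulates runs until a coverage-probability threshold is met, a
    sequencing-profile system that infers read-length and per-position error
    statistics from FASTQ data, a metagenome read simulator with
    lowercase-marked errors and ground-truth key files, and a Monte-Carlo
    oracle for validating the analytic coverage model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: GNU MPFR (>= 4.0), GNU GMP
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
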