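Package: dsdgates
Title: Domain-Level Simulation of DNA Strand-Displacement Logic Gates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Domain-level model of toehold-mediated DNA strand displacement
    for fluorophore/quencher reporter gates. Builds gate systems from
    structured specification files or from a built-in library of three-input
    OR, AND and MAJORITY gates, decides reporter release for any input
    combination via displacement-chain reachability, cross-checks decisions
    against a brute-force state-space oracle, compiles gates into stochastic
    reaction networks simulated with the exact Gillespie algorithm to give a
    fluorescence-style readout, and assigns orthogonal nucleotide sequences
    to domains with FASTA import and export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
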