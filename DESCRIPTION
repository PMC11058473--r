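Package: riboqueue
Title: Stochastic Modeling of Ribosome Queuing and Delayed Reinitiation
    on uORF-Regulated mRNA Leaders
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting translational control of stress-responsive
    mRNAs whose 5' leaders combine upstream open reading frames (uORFs),
    start-stop elements, near-cognate start codons, stem-loops and m6A
    motifs, modeled on the human ATF4 transcript leader. Provides a feature
    scanner (uORFs, Kozak context, DRACH/RRACH motifs, hairpin minimum free
    energy, frameshift signals, ribosome queue geometry), a continuous-time
    stochastic single-molecule simulator of scanning, ternary-complex
    acquisition, delayed reinitiation, stem-loop stalling and steric
    exclusion, emulated experimental readouts (reporter fold changes,
    footprint and disome profiles, RNase protection assays), and calibration
    of the kinetic parameters against reporter expression ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
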