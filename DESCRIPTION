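Package: peakstage
Title: Staged Neural-Network Classification of b-/y-Ion Peaks in Tandem MS Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Preprocessing for de novo peptide sequencing of CID tandem mass
    spectra. Reads Mascot generic format (MGF) peak lists, labels peaks of
    doubly charged tryptic peptides as b-, y- or unknown ions against the
    theoretical fragment ladder, computes fragmentation-aware peak features
    (intensity ranks, relative cleavage position, isotopologue log-odds,
    complementary-ion and neutral-loss evidence, flanking-residue evidence),
    and trains a two-stage feedforward neural network that assigns each peak
    posterior probabilities of being a b-ion, a y-ion or neither. Includes a
    sliding-window intensity baseline, precision/recall evaluation by peptide
    length, spectrum-graph construction with exhaustive candidate-peptide
    enumeration, and a synthetic-spectrum simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
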