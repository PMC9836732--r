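Package: coidiag
Title: Diagnostic Nucleotide Combinations and Morphological Keys for
    Species Identification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for character-based DNA barcoding diagnosis of marine
    annelids and similar taxa. Extracts per-species diagnostic nucleotide
    combinations from a labeled COI alignment, verifies and minimizes them,
    parses and formats the printed "start-end: MOTIF" diagnosis dialect,
    and identifies unaligned query sequences against diagnosis profiles by
    dynamic-programming placement onto the reference coordinate system.
    Also implements a morphological identification system for Northeast
    Atlantic Terebellides (uncini, branchiae and Methyl-Green staining
    typologies, a taxon-by-character matrix, and a dichotomous key engine),
    a synthetic-data generator with planted, known diagnostic structure,
    and parsers for museum specimen registries with bathymetric summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
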