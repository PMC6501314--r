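Package: gaxr
Title: Profiling of Grass Glucuronoarabinoxylan Oligosaccharides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for structural profiling of grass glucuronoarabinoxylan
    (GAX) oligosaccharides: a parser and serializer for the Faure one-letter
    heteroxylan nomenclature, monoisotopic mass and MALDI-CID fragment-ion
    prediction for reducing-end labelled xylooligosaccharides, rule-based
    in-silico digestion with GH10/GH11 endo-xylanases and exo-acting
    glycoside hydrolases, capillary-electrophoresis (DASH) trace alignment,
    dextran-ladder glucose-unit calibration and peak annotation against a
    packaged oligosaccharide mobility library, and side-chain
    substitution-frequency quantitation. A synthetic-data module generates
    polymers, digests, electropherograms and fragment spectra with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
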