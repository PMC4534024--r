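Package: pmf2de
Title: Peptide Mass Fingerprinting and 2-D Gel Differential Analysis for
    Saliva Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for classical gel-based proteomic
    biomarker discovery. Identifies 2-D gel spots by peptide mass
    fingerprinting (in-silico tryptic digestion, internal linear
    recalibration against standard peptides, monoisotopic mass matching at
    relative tolerance, binomial chance scoring, b/y fragment-ion
    confirmation), quantifies spots as percent volume, applies fold-change
    and group-specificity filters, and summarises binary-marker validation
    as sensitivity and specificity. Includes seeded generators for
    synthetic protein databases, MALDI peak lists with realistic
    corruptions, and two-group spot-volume tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
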