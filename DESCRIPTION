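Package: pspfinder
Title: Combinatorial Prediction and MS1 Screening of Proteasome-Generated
    Spliced Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exhaustive enumeration of proteasome-catalysed peptide splicing
    products (cis-normal, cis-reverse and trans) from polypeptide substrates,
    construction of theoretical m/z databases with tolerance-based clustering,
    matching against time-course MS1 peak lists with kinetic filtering, and
    generation of precursor inclusion lists for targeted MS/MS. Includes
    stable-isotope label variant calculation, b/y fragment-ion series,
    searchable FASTA export, a reproducible synthetic-digest simulator and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
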