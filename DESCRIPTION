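Package: orphanEnzymes
Title: Resolving Orphan Enzyme Activities by Census, Name Permutation, and
    Partial-Sequence Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for reconnecting experimentally characterized enzyme
    activities (EC numbers) with amino-acid sequences. Parses ENZYME-style
    flat-file catalogs, reconciles activities against multiple
    sequence-evidence sources to compute the putative-orphan set, generates
    synonym-robust permutations of enzyme names for literature search,
    identifies proteins from error-prone N-terminal (Edman) peptide reads
    and experimental molecular weights against a proteome, and classifies
    and summarizes curation outcomes. Includes seeded synthetic-fixture
    generators with recorded ground truth so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
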