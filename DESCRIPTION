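Package: hgvsr
Title: Parsing, Validation, Normalization and Projection of HGVS Sequence Variants
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for manipulating sequence variants described in HGVS
    nomenclature. Parses variant strings on genomic (g./m.), transcript
    (n./c.) and protein (p.) references into structured objects, formats
    them back with configurable display settings, validates them
    intrinsically and against reference data, normalizes them (allele
    trimming, 3' shifting and rewriting into the preferred edit type), and
    projects them between genome, transcript and protein coordinates
    through gapped transcript-genome alignments. Reference sequences, exon
    structures and alignments are served by a local fixture data provider;
    a seeded synthetic fixture generator builds multi-exon, dual-strand
    test genomes with alignment indels and mismatches.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
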