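Package: gyncomod
Title: Comparative Gynecological-Cancer Expression Analysis and
    Transcription-Factor Co-Binding Module Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for comparative cancer transcriptomics and
    regulatory genomics: unlogged two-group differential expression with
    probe collapsing and signed fold changes, cross-signature overlap and
    recurrence scoring against GMT collections, strand-aware promoter-window
    transcription-factor binding and up/down enrichment, and discovery of
    transcription-factor co-binding modules by normalizing a peak-overlap
    matrix and clustering it with average linkage on correlation distance.
    Includes a synthetic-data generator that plants differential expression,
    co-binding modules and recurrent signature genes so every stage is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
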