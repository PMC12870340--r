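Package: orphannot
Title: Dictionary-Based Annotation of Scientific Articles with Rare-Disease Concepts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates scientific-article records (title, abstract, keywords)
    with concepts from a rare-disease taxonomy structured like the OrphaNet
    nomenclature. Disease names and synonyms are normalized and compiled into
    a term dictionary; documents are annotated by token-boundary exact
    matching plus threshold-based fuzzy matching (normalized Levenshtein
    similarity over token windows), and concept assignments are propagated to
    near ancestors in the taxonomy hierarchy. Includes a multi-label
    evaluation suite (micro precision/recall/F1, CorrectRatio, ExactRatio,
    Wilson score intervals), a fully seeded synthetic generator of
    taxonomies, corpora and gold labels for end-to-end testing without
    external data, and bibliometric full-counting aggregation of annotations
    by disease, country and subject area.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    stringi,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
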