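Package: ontopath
Title: Ontology-Based Semantic Annotation of French Care-Coordination Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns unstructured French care-coordination notes into structured
    quantitative data. Provides a modular ontology model with fully defined
    (necessary-and-sufficient) concepts, an inference step that classifies
    thematic concepts under them, a dictionary-based semantic annotator with
    French negation handling, patient-by-concept count aggregation,
    annotation-quality evaluation (precision/recall/F-measure), and the
    association statistics used on the resulting matrices (OLS scans with
    Benjamini-Hochberg FDR and LogWorth ranking). Includes a seeded synthetic
    cohort generator emulating telegraphic French coordination notes with
    abbreviations, misspellings and negated mentions, so the whole pipeline is
    testable without access to a private clinical database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
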