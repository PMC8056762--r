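Package: ciflint
Title: Dictionary-Driven Semantic Validation of Crystallographic Information Files
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reads and writes CIF 1.1 and CIF 2.0 (STAR-derived) files and
    validates them against DDL1 and DDLm ontology dictionaries, in the style
    of the curation tooling used by open crystallographic databases. Checks
    cover data types, standard-uncertainty (concise parenthesis) notation,
    enumeration sets and concatenated enumeration sets, permitted ranges,
    looped-list eligibility, category keys and homogeneity, referential
    integrity, aliasing, container types, deprecation and dictionary
    application scope. Validation findings are emitted as structured,
    filter-friendly one-line messages with NOTE, WARNING and ERROR
    severities. A deterministic fixture generator builds toy dictionary
    pairs and CIF files with seeded violations together with the exact
    message multiset a correct validator must emit.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
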