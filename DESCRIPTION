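Package: taxodebug
Title: Debugging Is-A Structure and Mappings in Networked Taxonomies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and repairs defects in the is-a structure of taxonomies
    connected into a network by alignments. Candidate missing is-a relations
    and candidate missing mappings are derived from knowledge intrinsic to the
    network (derivable from the induced ontology but not from the local
    scope), validated by an expert or a scripted policy into missing and wrong
    relations, and repaired: wrong relations by removing axioms chosen from
    justifications via minimal hitting sets, missing relations by adding
    subsumptions ranked by informativeness. Includes readers and writers for a
    plain-text taxonomy dialect and an OBO 1.2 subset, a seeded synthetic
    network generator with planted defects and ground truth, a scripted
    session driver, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
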