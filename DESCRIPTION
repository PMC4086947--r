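Package: chresonym
Title: Contextual Taxonomic Name-Usage Databases with Citation-Based
    Species Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and analysing contextual taxonomic
    name-usage (chresonymy) databases: flat-file tables recording every
    occurrence of a scientific name in the literature together with the
    context of its use (specimen, location, citation, or none), a
    chronological resolver that propagates currently-accepted species
    identities through citation chains with automatic "in part"
    annotation, spelling-variant normalisation of epithets,
    cross-reference indices (specific names, compound names,
    publications, species), and a deterministic static-site generator.
    Includes a synthetic literature-network generator with planted
    ground truth and a fixed-point reference resolver for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
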