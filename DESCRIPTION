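Package: rulerail
Title: Railroad Diagrams for Rule-Based Biochemical Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses rule-based model specifications written in a subset of the
    BioNetGen language (molecule types, seed species, observables and reaction
    rules), derives the actions performed by each reaction rule (bond
    formation and breakage, site state changes, molecule synthesis and
    degradation) by structural comparison of reactant and product patterns,
    and renders every molecule, species, observable and rule as a railroad
    style diagram in standalone SVG. Diagrams follow color-agnostic
    conventions: every semantic distinction is carried by a glyph, a dash
    pattern or a label in addition to an overridable color class, so the
    output remains interpretable in monochrome. Includes a seeded synthetic
    model generator with construction-time ground-truth action sets for
    property-based testing, and a small command-line front end.
License: MIT
Encoding: UTF-8
Imports:
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
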