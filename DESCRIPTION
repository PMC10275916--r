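Package: genrecon
Title: Draft Genome-Scale Metabolic Reconstruction with Parsimonious-Flux Gap-Filling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds draft genome-scale metabolic network reconstructions (GENREs)
    from protein-annotation evidence in a ModelSEED-style namespace, curates a
    universal reaction database by elemental and charge balance, gap-fills drafts
    with a two-step parsimonious-flux linear program under media constraints, and
    writes analysis-ready SBML (Level 3, FBC v2) models. Includes flux balance
    analysis, parsimonious FBA, gene essentiality screening and seeded
    hit-and-run flux sampling, together with a deterministic toy-fixture
    generator with known ground truth for every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
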