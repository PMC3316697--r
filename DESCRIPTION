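Package: stygosim
Title: Colonization Models and Sister-Clade Tests for Isolated Aquifer Radiations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests of speciation mode for subterranean radiations in isolated
    calcrete aquifers. Implements closed-form and Monte Carlo versions of the
    repeated-colonization and single-colonization (within-aquifer
    diversification) null models for the frequency of sympatric sister species,
    5/95-percentile randomization bands, detection of sympatric sister pairs
    and triplets on annotated time-calibrated phylogenies, surface versus
    subterranean lineage-through-time curves, and a seeded synthetic-data
    generator with known colonization ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    parallel,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
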